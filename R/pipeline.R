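# End-to-end MV vortex ring extraction.

#' Run configuration
#'
#' All tunables of the extraction pipeline with their defaults. Internal
#' units are SI; lengths in configuration are mm.
#'
#' @param margin bounding-box margin in voxels per axis.
#' @param hodgeTol relative tolerance of the curl-curl solver.
#' @param hodgeMaxIter iteration cap of the solver.
#' @param spatialSigma,medianSize,temporalSigma Q filtering parameters
#'   (voxels / window edge / frames), see [smoothQSeries()].
#' @param kappaW vortex-frame window factor, see [vortexFrameWindow()].
#' @param minPeakSeparation minimal frame separation of the E and A peaks.
#' @param minVoxels minimal candidate component size.
#' @param dFloor floor (mm) on the candidate-factor distance.
#' @param rho blood density (kg/m^3).
#' @param maxStreamLen maximal streamline steps per direction.
#' @param endDiastolicFrame frame used by the static-mask experiment and
#'   for long-axis estimation.
#' @param sliceAxis short-axis stacking axis (for slice subsampling).
#' @param longAxis optional unit 3-vector; when `NULL` it is estimated from
#'   the end-diastolic mask (first principal axis of the voxel positions).
#' @param units declared velocity unit of input files.
#' @param spacing,frameDuration optional geometry overrides for file input.
#' @param trace named list of [traceConfig()] overrides.
#' @param seed RNG seed recorded with the run (the extraction itself is
#'   deterministic; the seed governs phantom simulation).
#' @return a named list.
#' @export
mvringConfig <- function(margin = 2L, hodgeTol = 1e-6, hodgeMaxIter = 30000L,
                         spatialSigma = 1, medianSize = 3L, temporalSigma = 1,
                         kappaW = 0.5, minPeakSeparation = 3L, minVoxels = 5L,
                         dFloor = 1, rho = 1060, maxStreamLen = 1000L,
                         endDiastolicFrame = 1L, sliceAxis = 3L,
                         longAxis = NULL, units = "m/s", spacing = NULL,
                         frameDuration = NULL, trace = list(), seed = 1L) {
  list(margin = as.integer(margin), hodgeTol = hodgeTol,
       hodgeMaxIter = as.integer(hodgeMaxIter), spatialSigma = spatialSigma,
       medianSize = as.integer(medianSize), temporalSigma = temporalSigma,
       kappaW = kappaW, minPeakSeparation = as.integer(minPeakSeparation),
       minVoxels = as.integer(minVoxels), dFloor = dFloor, rho = rho,
       maxStreamLen = as.integer(maxStreamLen),
       endDiastolicFrame = as.integer(endDiastolicFrame),
       sliceAxis = as.integer(sliceAxis), longAxis = longAxis, units = units,
       spacing = spacing, frameDuration = frameDuration, trace = trace,
       seed = as.integer(seed))
}

#' Estimate the LV long axis from a mask
#'
#' First principal axis of the mask voxel positions of the end-diastolic
#' frame, oriented from base (the wider end) to apex.
#'
#' @param masks a [MaskSeries-class].
#' @param frame frame to use.
#' @return unit 3-vector.
#' @export
estimateLongAxis <- function(masks, frame = 1L) {
  m <- masks@frames[[frame]]
  idx <- arrayInd(which(m), dim(m))
  pos <- voxelToPhysical(masks@grid, idx)
  ctr <- colMeans(pos)
  X <- sweep(pos, 2, ctr, "-")
  ax <- svd(X, nu = 0)$v[, 1]
  # orientation: base (wider cross-section) to apex
  proj <- drop(X %*% ax)
  lat <- sqrt(rowSums((X - outer(proj, ax))^2))
  wNeg <- mean(lat[proj < 0]); wPos <- mean(lat[proj >= 0])
  if (is.finite(wNeg) && is.finite(wPos) && wPos > wNeg) ax <- -ax
  ax / sqrt(sum(ax^2))
}

# empty result helper
.emptyResult <- function(velocity, box, qsObj, longAxis, config) {
  n <- velocity@grid@nFrames
  pt <- parameterTimecourse(vector("list", n), vector("list", n), velocity,
                            longAxis, rho = config$rho)
  new("MVRingResult", grid = velocity@grid, box = box, qseries = qsObj,
      cores = vector("list", n), regions = vector("list", n),
      params = pt$params, peaks = pt$peaks,
      presence = rep(FALSE, n), longAxis = longAxis, config = config)
}

#' Extract the MV vortex ring from a 4D-flow series
#'
#' Runs the full four-step pipeline: (1) divergence-free field computation
#' in the LV bounding box, (2) Q-criterion analysis with frame-specific
#' thresholds and candidate selection, (3) predictor-corrector core tracing
#' with temporal tracking, (4) streamline region growing with pruning, and
#' finally the per-frame parameter table.
#'
#' @param velocity a [VelocitySeries-class].
#' @param masks an aligned [MaskSeries-class].
#' @param config configuration from [mvringConfig()].
#' @param verbose print progress.
#' @return an [MVRingResult-class].
#' @export
extractVortexRing <- function(velocity, masks, config = mvringConfig(),
                              verbose = FALSE) {
  grid <- velocity@grid
  stopifnot(identical(grid@shape, masks@grid@shape))
  n <- grid@nFrames
  if (masks@grid@nFrames == 1L && n > 1L) {
    # a single (static) segmentation serves every cardiac frame
    g2 <- masks@grid; g2@nFrames <- n
    masks <- MaskSeries(g2, rep(masks@frames, n), masks@provenance)
  }
  stopifnot(masks@grid@nFrames == n)
  say <- function(...) if (verbose) message(sprintf(...))

  box <- boundingBox(masks, config$margin)
  say("bounding box: %s voxels",
      paste(box@upper - box@lower, collapse = " x "))
  longAxis <- config$longAxis %||%
    estimateLongAxis(masks, config$endDiastolicFrame)
  longAxis <- longAxis / sqrt(sum(longAxis^2))

  # Step 1: divergence-free part
  rSeries <- divergenceFreePart(velocity, box, tol = config$hodgeTol,
                                maxIter = config$hodgeMaxIter,
                                verbose = verbose)
  cgrid <- rSeries@grid
  spacingM <- cgrid@spacing / 1000
  mlist <- lapply(masks@frames, .cropArray, box)

  # Step 2: Q analysis
  qRaw <- lapply(rSeries@frames, qField, spacing = spacingM)
  qSm <- smoothQSeries(qRaw, config$spatialSigma, config$medianSize,
                       config$temporalSigma)
  qm <- applyMasks(qSm, mlist)
  ft <- frameThresholds(qm, mlist)
  win <- tryCatch(
    vortexFrameWindow(ft$maxCurve, ft$thresholds, config$kappaW,
                      config$minPeakSeparation),
    error = function(e) NULL)
  qsObj <- new("QSeries", grid = cgrid, box = box, qFrames = qm,
               thresholds = ft$thresholds, maxCurve = ft$maxCurve,
               maxLocations = ft$maxLocations,
               vortexFrames = if (is.null(win)) integer(0) else win$vortexFrames,
               peakFrames = if (is.null(win)) integer(0) else win$peakFrames)
  if (is.null(win)) {
    warning("no vortex activity detected")
    return(.emptyResult(velocity, box, qsObj, longAxis, config))
  }
  say("vortex window: frames %s; peaks %s",
      paste(range(win$vortexFrames), collapse = "-"),
      paste(win$peakFrames, collapse = ", "))

  pc <- firstPrincipalComponent(qm, ft$thresholds, win$vortexFrames)
  pc@w1MaxLocation <- drop(voxelToPhysical(cgrid, pc@w1MaxVoxel))

  candidates <- vector("list", n)
  for (f in win$vortexFrames) {
    regs <- thresholdRegions(qm[[f]], ft$thresholds[f], config$minVoxels)
    if (!length(regs)) next
    cands <- lapply(regs, function(vx) {
      cf <- candidateFactor(vx, pc, cgrid, longAxis, config$dFloor)
      new("VortexCandidate", voxels = vx, fc = cf$fc, dMax = cf$dMax,
          centroid = colMeans(voxelToPhysical(cgrid, vx)),
          frame = as.integer(f))
    })
    candidates[[f]] <- selectCandidates(cands)
  }

  # Step 3: core tracing with temporal tracking
  vortFrames <- vector("list", n)
  for (f in win$vortexFrames)
    vortFrames[[f]] <- discreteCurl(rSeries@frames[[f]], spacingM)
  cfg <- do.call(traceConfig, c(list(cgrid), config$trace))
  cores <- trackCores(candidates, qsObj, vortFrames, cfg)

  # Step 4: region growing. Streamlines terminate on the *unfiltered* Q of
  # the divergence-free field: the filtered Q drives thresholds and
  # candidate detection, but its spatial smoothing systematically inflates
  # the Q > 0 domain (by about the kernel width, i.e. a full slice along
  # the coarsest axis), which would bias the ring volume upward.
  qPhys <- applyMasks(qRaw, mlist)
  regions <- vector("list", n)
  for (f in seq_len(n)) {
    cl <- cores[[f]]
    if (is.null(cl) || !isTRUE(cl@isMVRing)) next
    seeds <- seedPoints(cl, cgrid, mask = mlist[[f]])
    rg <- growRegion(seeds, rSeries@frames[[f]], qPhys[[f]], mlist[[f]], cgrid,
                     maxLen = config$maxStreamLen, frame = f)
    rg <- pruneRegion(rg, dims = cgrid@shape)
    if (!nrow(rg@voxels)) next
    # back to full-grid indices
    rg@voxels <- sweep(rg@voxels, 2, box@lower, "+")
    regions[[f]] <- rg
  }

  pt <- parameterTimecourse(cores, regions, velocity, longAxis,
                            rho = config$rho)
  new("MVRingResult", grid = grid, box = box, qseries = qsObj,
      cores = cores, regions = regions, params = pt$params,
      peaks = pt$peaks, presence = pt$params$present,
      longAxis = longAxis, config = config)
}
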