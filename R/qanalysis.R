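# Q-criterion computation, filtering, frame-specific thresholds, the
# vortex-frame window, and MV vortex ring candidate selection.

#' Q-criterion field
#'
#' Computes `Q = 1/2 (||Omega||_F^2 - ||S||_F^2)` per voxel, where `S` and
#' `Omega` are the symmetric (strain-rate) and antisymmetric (spin) parts of
#' the velocity gradient tensor. Voxels with `Q > 0` are vortical: rotation
#' dominates strain. Equivalent to `-1/2 tr(G^2)` for the gradient `G`.
#'
#' @param field vector volume `c(nx, ny, nz, 3)` in m/s.
#' @param spacing numeric(3) voxel spacing in metres (for Q in 1/s^2).
#' @return scalar volume of Q values (s^-2).
#' @export
qField <- function(field, spacing) {
  G <- velocityGradientTensor(field, spacing)
  q <- array(0, dim(field)[1:3])
  for (i in 1:3)
    for (j in 1:3)
      q <- q - G[, , , i, j] * G[, , , j, i]
  q / 2
}

#' Spatio-temporal filtering of a Q series
#'
#' Per frame: Gaussian blur (sigma in voxels per axis), then a cubic median
#' filter, then per-voxel Gaussian smoothing along the frame axis with
#' cyclic boundary (the cardiac cycle is periodic). The order of the three
#' stages is fixed. Removes noise and vortex structures with a short
#' lifetime.
#'
#' @param qFrames list of scalar volumes.
#' @param spatialSigma Gaussian sigma in voxels (scalar or per axis).
#' @param medianSize odd edge length of the cubic median window (1 = off).
#' @param temporalSigma Gaussian sigma in frames (0 = off).
#' @return list of filtered scalar volumes.
#' @export
smoothQSeries <- function(qFrames, spatialSigma = 1, medianSize = 3L,
                          temporalSigma = 1) {
  out <- lapply(qFrames, function(q) {
    q <- .gaussSmooth3(q, spatialSigma)
    .medianFilter3(q, medianSize)
  })
  .temporalGaussCyclic(out, temporalSigma)
}

#' Apply LV masks to Q frames
#'
#' Q outside the mask is set to zero and thereby excluded from maxima,
#' thresholds and candidate regions.
#'
#' @param qFrames list of scalar volumes.
#' @param masks a [MaskSeries-class] on the same grid (or a list of logical
#'   arrays of matching shape).
#' @export
applyMasks <- function(qFrames, masks) {
  mf <- if (is(masks, "MaskSeries")) masks@frames else masks
  stopifnot(length(mf) == length(qFrames))
  mapply(function(q, m) {
    stopifnot(identical(dim(q), dim(m)))
    q[!m] <- 0
    q
  }, qFrames, mf, SIMPLIFY = FALSE)
}

#' Frame-specific Q thresholds
#'
#' For each frame n the location of the maximum of the masked Q field is
#' recorded. The threshold of frame i is the mean over all N frames n of
#' `Q_i` evaluated at those N locations. The per-frame maximum curve
#' `maxCurve[i] = Q_i` at its own argmax is returned alongside. A frame
#' whose masked Q is identically zero contributes its first mask voxel as
#' the argmax location.
#'
#' @param qFrames list of masked scalar volumes.
#' @param masks a [MaskSeries-class] or list of logical arrays.
#' @return list with `thresholds` (numeric N), `maxCurve` (numeric N) and
#'   `maxLocations` (N x 3 matrix of 1-based voxel indices).
#' @export
frameThresholds <- function(qFrames, masks) {
  mf <- if (is(masks, "MaskSeries")) masks@frames else masks
  n <- length(qFrames)
  dims <- dim(qFrames[[1]])
  locs <- matrix(0L, n, 3)
  lin <- integer(n)
  for (i in seq_len(n)) {
    q <- qFrames[[i]]
    if (any(q > 0)) {
      lin[i] <- which.max(q)
    } else {
      inMask <- which(mf[[i]])
      if (!length(inMask)) inMask <- 1L
      lin[i] <- inMask[1]
    }
    locs[i, ] <- arrayInd(lin[i], dims)
  }
  thr <- vapply(seq_len(n), function(i) mean(qFrames[[i]][lin]), numeric(1))
  thr <- pmax(thr, 0)
  maxCurve <- vapply(seq_len(n), function(i) qFrames[[i]][lin[i]], numeric(1))
  list(thresholds = thr, maxCurve = maxCurve, maxLocations = locs)
}

#' Vortex-frame window and the two peak frames
#'
#' Frames with `maxCurve >= kappaW * mean(thresholds)` are "active". The
#' vortex-frame window is the shortest cyclically contiguous interval that
#' covers every active frame (the complement of the largest cyclic gap
#' between active frames); it contains the global maximum of the curve and
#' bridges the diastasis between the E- and A-wave activity bursts. The two
#' peak frames are the two largest local maxima of the curve inside the
#' window separated by at least 3 frames; with a single local maximum both
#' peaks coincide.
#'
#' @param maxCurve numeric(N) per-frame Q maxima.
#' @param thresholds numeric(N) frame-specific thresholds.
#' @param kappaW window factor; active means
#'   `maxCurve >= kappaW * mean(thresholds)`.
#' @param minPeakSeparation minimal frame separation of the two peaks.
#' @return list with `vortexFrames` (frame indices in cyclic order) and
#'   `peakFrames` (integer(2), in window order: E first).
#' @export
vortexFrameWindow <- function(maxCurve, thresholds, kappaW = 0.5,
                              minPeakSeparation = 3L) {
  n <- length(maxCurve)
  stopifnot(n >= 3L, length(thresholds) == n)
  lev <- kappaW * mean(thresholds)
  active <- which(maxCurve >= lev & maxCurve > 0)
  if (length(active) < 2L)
    stop("no vortex activity detected (window shorter than 2 frames)")
  # largest cyclic gap between consecutive active frames; the window is its
  # complement
  gaps <- diff(c(active, active[1] + n)) # cyclic successor distances
  gi <- which.max(gaps)
  startFrame <- active[(gi %% length(active)) + 1L]
  len <- n - max(gaps) + 1L
  window <- ((startFrame - 1L + seq_len(len) - 1L) %% n) + 1L
  if (length(window) < 2L)
    stop("no vortex activity detected (window shorter than 2 frames)")

  # local maxima of maxCurve along the window sequence
  wc <- maxCurve[window]
  L <- length(wc)
  isMax <- vapply(seq_len(L), function(p) {
    left <- if (p > 1L) wc[p - 1L] else -Inf
    right <- if (p < L) wc[p + 1L] else -Inf
    wc[p] > 0 && wc[p] >= left && wc[p] >= right
  }, logical(1))
  peaksPos <- which(isMax)
  peaksPos <- peaksPos[order(wc[peaksPos], decreasing = TRUE)]
  if (!length(peaksPos))
    peaksPos <- which.max(wc)
  p1 <- peaksPos[1]
  p2 <- NA_integer_
  for (p in peaksPos[-1]) {
    if (abs(p - p1) >= minPeakSeparation) { p2 <- p; break }
  }
  if (is.na(p2)) p2 <- p1
  pk <- sort(c(p1, p2))
  list(vortexFrames = as.integer(window),
       peakFrames = as.integer(window[pk]))
}

# 26-connected components of a voxel set given as linear indices;
# returns a list of M x 3 matrices of 1-based array indices
.connectedComponents26 <- function(linIdx, dims) {
  if (!length(linIdx)) return(list())
  nvox <- length(linIdx)
  id <- integer(prod(dims))
  id[linIdx] <- seq_len(nvox)
  sub <- arrayInd(linIdx, dims)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE] # 13 forward offsets
  eFrom <- integer(0); eTo <- integer(0)
  for (o in seq_len(nrow(offs))) {
    ni <- sub[, 1] + offs[o, 1]
    nj <- sub[, 2] + offs[o, 2]
    nk <- sub[, 3] + offs[o, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
      nk >= 1L & nk <= dims[3]
    if (!any(ok)) next
    nlin <- ni[ok] + (nj[ok] - 1L) * dims[1] + (nk[ok] - 1L) * dims[1] * dims[2]
    nid <- id[nlin]
    hit <- nid > 0L
    eFrom <- c(eFrom, which(ok)[hit])
    eTo <- c(eTo, nid[hit])
  }
  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  if (length(eFrom))
    g <- igraph::add_edges(g, rbind(eFrom, eTo))
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(nvox), memb), function(ix) sub[ix, , drop = FALSE])
}

#' Thresholded vortex regions of one frame
#'
#' 26-connected components of `{Q > thr}`; components with fewer than
#' `minVoxels` voxels are discarded (they are below the smoothing scale).
#'
#' @param qFrame masked scalar Q volume.
#' @param thr threshold (>= 0).
#' @param minVoxels minimal component size retained.
#' @return list of M x 3 matrices of 1-based voxel indices (possibly empty).
#' @export
thresholdRegions <- function(qFrame, thr, minVoxels = 5L) {
  stopifnot(thr >= 0)
  lin <- which(qFrame > thr)
  comps <- .connectedComponents26(lin, dim(qFrame))
  comps[vapply(comps, nrow, integer(1)) >= minVoxels]
}

#' First principal component of the thresholded Q fields over time
#'
#' The thresholded Q frames of the vortex-frame window (values where
#' `Q > thr_i`, zero elsewhere) form a voxels x frames data matrix. Each
#' voxel's time course is centered and the first left singular vector,
#' reshaped to the volume, is the spatial map `w1` of the dominant temporal
#' Q pattern. The sign is fixed so that `w1 >= 0` at the location of the
#' global Q maximum over the window.
#'
#' @param qFrames list of masked Q volumes (all N frames).
#' @param thresholds numeric(N) frame thresholds.
#' @param window integer vector of vortex-frame indices (>= 2 frames).
#' @return a [PCFields-class].
#' @export
firstPrincipalComponent <- function(qFrames, thresholds, window) {
  stopifnot(length(window) >= 2L)
  dims <- dim(qFrames[[1]])
  X <- vapply(window, function(i) {
    q <- qFrames[[i]]
    q[q <= thresholds[i]] <- 0
    as.numeric(q)
  }, numeric(prod(dims)))
  if (all(X == 0)) stop("thresholded Q fields are identically zero")
  # global (unthresholded-argmax) Q maximum over the window, for the sign fix
  gmax <- which.max(vapply(window, function(i) max(qFrames[[i]]), numeric(1)))
  gmaxVox <- which.max(as.numeric(qFrames[[window[gmax]]]))
  rm <- rowMeans(X)
  Xc <- X - rm
  sv <- svd(Xc, nu = 1, nv = 0)
  w1 <- sv$u[, 1]
  if (w1[gmaxVox] < 0) w1 <- -w1
  evr <- sv$d[1]^2 / sum(sv$d^2)
  w1MaxVoxel <- arrayInd(which.max(w1), dims)[1, ]
  new("PCFields", w1 = array(w1, dims),
      explainedVarianceRatio = evr,
      w1MaxLocation = numeric(0), # set by the caller that knows the grid
      w1MaxVoxel = as.integer(w1MaxVoxel))
}

#' Candidate factor and maximal long-axis distance of a vortex region
#'
#' `fc = sum(w1 over the region voxels) / dMax`, where `dMax` is the
#' maximal absolute long-axis-projected distance (mm) of the region voxels
#' to the location of the `w1` maximum. `fc` scores how likely the region
#' belongs to the MV vortex ring. A floor of `dFloor` mm protects against
#' division blow-up for regions sitting at the `w1` maximum.
#'
#' @param voxelIdx M x 3 matrix of 1-based voxel indices of the region.
#' @param pc a [PCFields-class] with `w1MaxLocation` set (mm).
#' @param grid the [FlowGrid-class] the voxel indices refer to.
#' @param longAxis unit 3-vector, LV long-axis direction.
#' @param dFloor minimal `dMax` in mm.
#' @return list with `fc` and `dMax`.
#' @export
candidateFactor <- function(voxelIdx, pc, grid, longAxis, dFloor = 1) {
  stopifnot(nrow(voxelIdx) > 0)
  pos <- voxelToPhysical(grid, voxelIdx)
  proj <- abs(drop(sweep(pos, 2, pc@w1MaxLocation, "-") %*% longAxis))
  dMax <- max(proj)
  dEff <- max(dMax, dFloor)
  w1sum <- sum(pc@w1[voxelIdx])
  list(fc = w1sum / dEff, dMax = dMax)
}

#' Select up to two MV vortex ring candidates
#'
#' Regions whose `dMax` is at least twice the minimal `dMax` of all regions
#' are excluded; the remaining regions are ranked by candidate factor and
#' the top two are kept.
#'
#' @param candidates list of [VortexCandidate-class] objects.
#' @return list of at most two [VortexCandidate-class] objects, highest
#'   factor first.
#' @export
selectCandidates <- function(candidates) {
  if (!length(candidates)) return(list())
  dmax <- vapply(candidates, function(x) x@dMax, numeric(1))
  keep <- dmax < 2 * min(dmax)
  cand <- candidates[keep]
  fc <- vapply(cand, function(x) x@fc, numeric(1))
  cand[order(fc, decreasing = TRUE)][seq_len(min(2L, length(cand)))]
}
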