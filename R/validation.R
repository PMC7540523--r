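# Segmentation-perturbation experiments and agreement statistics.

#' Subsample short-axis mask slices
#'
#' Emulates sparser manual segmentation: only every k-th segmented slice
#' along the short-axis stacking axis is retained (starting at the first
#' segmented slice); the slices in between are filled from the nearest
#' retained slice, ties toward the base (lower slice index). With a base
#' slice distance d this yields an effective slice distance of k * d.
#'
#' @param masks a [MaskSeries-class].
#' @param k subsampling factor (k = 1 is the identity).
#' @param sliceAxis axis of slice stacking (default 3, the z axis).
#' @return a [MaskSeries-class] with provenance `"subsampled-kd"`.
#' @export
subsampleMaskSlices <- function(masks, k, sliceAxis = 3L) {
  stopifnot(k >= 1L)
  if (k == 1L) return(masks)
  dims <- masks@grid@shape
  nS <- dims[sliceAxis]
  sliceSum <- function(m, s) {
    idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    idx[[sliceAxis]] <- s
    sum(m[idx[[1]], idx[[2]], idx[[3]]])
  }
  out <- masks
  for (f in seq_along(masks@frames)) {
    m <- masks@frames[[f]]
    seg <- which(vapply(seq_len(nS), function(s) sliceSum(m, s) > 0, logical(1)))
    if (!length(seg)) next
    retained <- seg[seq(1L, length(seg), by = k)]
    if (length(retained) < 2L)
      stop("fewer than 2 retained slices at k = ", k)
    m2 <- array(FALSE, dims)
    for (s in seg) {
      d <- abs(retained - s)
      src <- retained[which.min(d)] # which.min takes the first: tie to base
      ia <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      ib <- ia
      ia[[sliceAxis]] <- s; ib[[sliceAxis]] <- src
      m2[ia[[1]], ia[[2]], ia[[3]]] <- m[ib[[1]], ib[[2]], ib[[3]]]
    }
    out@frames[[f]] <- m2
  }
  out@provenance <- "subsampled-kd"
  out
}

#' Static end-diastolic mask
#'
#' Applies the fully segmented mask of one frame (normally end-diastole) to
#' all frames.
#'
#' @param masks a [MaskSeries-class].
#' @param frame index of the frame to replicate.
#' @return a [MaskSeries-class] with provenance `"static-end-dia"`.
#' @export
staticMask <- function(masks, frame = 1L) {
  stopifnot(frame >= 1L, frame <= length(masks@frames))
  out <- masks
  out@frames <- rep(masks@frames[frame], length(masks@frames))
  out@provenance <- "static-end-dia"
  out
}

# shift a logical array by one voxel along an axis, padding with FALSE
.shift1 <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (by > 0) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Erode or dilate masks by one voxel
#'
#' Morphological erosion/dilation with a 6-connected (face-adjacent,
#' cross-shaped) structuring element, the most conservative single-voxel
#' element on an anisotropic grid. Voxels outside the array are treated as
#' background.
#'
#' @param masks a [MaskSeries-class].
#' @param mode `"erode"` or `"dilate"`.
#' @return a [MaskSeries-class] with provenance set accordingly.
#' @export
morphMask <- function(masks, mode = c("erode", "dilate")) {
  mode <- match.arg(mode)
  out <- masks
  for (f in seq_along(masks@frames)) {
    m <- masks@frames[[f]]
    acc <- m
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      s <- .shift1(m, ax, by)
      acc <- if (mode == "erode") acc & s else acc | s
    }
    if (mode == "erode" && !any(acc))
      warning("erosion emptied mask frame ", f)
    out@frames[[f]] <- acc
  }
  out@provenance <- if (mode == "erode") "eroded" else "dilated"
  out
}

#' Dice similarity coefficient of two voxel sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both sets are
#' empty. Accepts M x 3 index matrices, logical arrays or
#' [VortexRegion-class] objects (mixing is allowed when shapes agree).
#'
#' @param a,b voxel sets.
#' @param dims grid dims used to linearize index matrices.
#' @export
diceCoefficient <- function(a, b, dims = NULL) {
  tolin <- function(x) {
    if (is(x, "VortexRegion")) x <- x@voxels
    if (is.logical(x)) return(which(x))
    if (is.null(dims)) stop("dims needed for index-matrix input")
    as.integer(x[, 1] + (x[, 2] - 1) * dims[1] +
                 (x[, 3] - 1) * dims[1] * dims[2])
  }
  la <- tolin(a); lb <- tolin(b)
  if (!length(la) && !length(lb)) return(1)
  2 * length(intersect(la, lb)) / (length(la) + length(lb))
}

# rasterize a polyline to voxels: sample each segment finely, mark entered
# voxels, dilate by one 26-shell
.rasterizeCore <- function(pts, grid, closed = FALSE) {
  if (is.null(dim(pts)) || nrow(pts) == 0) return(matrix(integer(0), 0, 3))
  if (closed && nrow(pts) > 1) pts <- rbind(pts, pts[1, ])
  step <- min(grid@spacing) / 2
  dense <- pts[1, , drop = FALSE]
  if (nrow(pts) > 1) {
    segs <- lapply(seq_len(nrow(pts) - 1), function(i) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      L <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
            a[3] + t * (b[3] - a[3]))
    })
    dense <- do.call(rbind, segs)
  }
  vox <- unique(round(physicalToVoxel(grid, dense)))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  vox <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
    sweep(vox, 2, offs[o, ], "+"))))
  ok <- vox[, 1] >= 1 & vox[, 1] <= grid@shape[1] &
    vox[, 2] >= 1 & vox[, 2] <= grid@shape[2] &
    vox[, 3] >= 1 & vox[, 3] <= grid@shape[3]
  matrix(as.integer(vox[ok, ]), ncol = 3)
}

#' Dice overlap of two vortex core polylines
#'
#' Each polyline is rasterized to the voxel grid (voxels whose cells the
#' line enters, dilated by one 26-neighbourhood shell to absorb sub-voxel
#' offsets) and the Dice coefficient of the two voxel sets is returned.
#'
#' @param coreA,coreB [VortexCore-class] objects (or point matrices).
#' @param grid the [FlowGrid-class] used for rasterization.
#' @export
coreDice <- function(coreA, coreB, grid) {
  getp <- function(x) if (is(x, "VortexCore")) list(p = x@points, cl = x@closed)
  else list(p = x, cl = FALSE)
  a <- getp(coreA); b <- getp(coreB)
  ra <- .rasterizeCore(a$p, grid, a$cl)
  rb <- .rasterizeCore(b$p, grid, b$cl)
  if (!nrow(ra) && !nrow(rb)) return(1)
  if (!nrow(ra) || !nrow(rb)) return(0)
  diceCoefficient(ra, rb, dims = grid@shape)
}

#' Cohen's kappa of a 2x2 presence confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the observed agreement
#' `p_o = (a + d) / n` and the chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. When `p_e = 1` (a degenerate
#' margin) kappa is defined as 1 if `p_o = 1` and 0 otherwise.
#'
#' @param m a [ConfusionMatrix2x2-class], or a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))` with rows = automated absent/present and
#'   columns = reference absent/present.
#' @export
cohenKappa <- function(m) {
  if (is(m, "ConfusionMatrix2x2")) {
    a <- m@a; b <- m@b; cc <- m@c; d <- m@d
  } else {
    stopifnot(is.matrix(m), all(dim(m) == 2))
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  }
  n <- a + b + cc + d
  stopifnot(n > 0)
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# presence confusion of two logical vectors (automated vs reference)
.presenceConfusion <- function(auto, ref) {
  confusionMatrix2x2(a = sum(!auto & !ref), b = sum(!auto & ref),
                     c = sum(auto & !ref), d = sum(auto & ref))
}

#' Run a segmentation-perturbation experiment
#'
#' Derives the perturbed mask series for `condition`, runs the full
#' extraction under it, and compares against the reference extraction:
#' per-frame presence agreement (Cohen's kappa), mean core and region Dice
#' over the frames where both detect an MV ring, and percentage errors of
#' the E/A peak parameters.
#'
#' @param velocity a [VelocitySeries-class].
#' @param referenceMasks the reference [MaskSeries-class].
#' @param condition one of `"reference"`, `"2d" ... "6d"`, `"end-dia"`,
#'   `"erode"`, `"dilate"`.
#' @param config configuration list from [mvringConfig()].
#' @param reference optional precomputed reference [MVRingResult-class]
#'   (computed when missing).
#' @return list with `condition`, `kappa`, `coreDice`, `regionDice`,
#'   `peakErrors` (percent), `result` and `reference`.
#' @export
runExperiment <- function(velocity, referenceMasks, condition, config = mvringConfig(),
                          reference = NULL) {
  cond <- match.arg(condition, c("reference", "2d", "3d", "4d", "5d", "6d",
                                 "end-dia", "erode", "dilate"))
  masks <- switch(cond,
    reference = referenceMasks,
    "end-dia" = staticMask(referenceMasks, config$endDiastolicFrame),
    erode = morphMask(referenceMasks, "erode"),
    dilate = morphMask(referenceMasks, "dilate"),
    subsampleMaskSlices(referenceMasks, as.integer(substr(cond, 1, 1)),
                        config$sliceAxis))
  if (is.null(reference))
    reference <- extractVortexRing(velocity, referenceMasks, config)
  res <- extractVortexRing(velocity, masks, config)
  kap <- cohenKappa(.presenceConfusion(res@presence, reference@presence))
  both <- which(res@presence & reference@presence)
  cd <- rd <- numeric(0)
  for (f in both) {
    cd <- c(cd, coreDice(res@cores[[f]], reference@cores[[f]], velocity@grid))
    rd <- c(rd, diceCoefficient(res@regions[[f]], reference@regions[[f]],
                                dims = velocity@grid@shape))
  }
  peakErr <- function(p, q) {
    cols <- c("vol_mL", "vort_max_s1", "vort_mean_s1", "ekin_abs_mJ",
              "ekin_rel_Jm3", "alpha_deg", "ci")
    if (is.null(p) || is.null(q)) return(setNames(rep(NA_real_, length(cols)), cols))
    vapply(cols, function(cn) {
      pv <- p[[cn]]; qv <- q[[cn]]
      if (is.null(pv) || is.null(qv) || !is.finite(pv) || !is.finite(qv) ||
          qv == 0) return(NA_real_)
      100 * (pv - qv) / qv
    }, numeric(1))
  }
  perr <- list(E = peakErr(res@peaks$E, reference@peaks$E),
               A = peakErr(res@peaks$A, reference@peaks$A))
  list(condition = cond, kappa = kap,
       coreDice = if (length(cd)) mean(cd) else NA_real_,
       regionDice = if (length(rd)) mean(rd) else NA_real_,
       peakErrors = perr, result = res, reference = reference)
}
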