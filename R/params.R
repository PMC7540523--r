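# The six quantitative MV vortex ring parameters.

#' Vorticity field of a velocity frame
#'
#' Curl of the (un-decomposed) velocity field by central finite differences;
#' shares the stencils of [discreteCurl()].
#'
#' @param field vector volume `c(dims, 3)` in m/s.
#' @param spacing numeric(3) voxel spacing in metres.
#' @return vector volume of vorticity (1/s).
#' @export
vorticityField <- function(field, spacing) discreteCurl(field, spacing)

#' Maximum and mean vorticity of a ring region
#'
#' Both statistics are taken over the vorticity magnitude at the region
#' voxels. To be robust to outliers the "maximum" is the 95th percentile
#' (linear interpolation between order statistics); the mean is the
#' arithmetic mean.
#'
#' @param region a [VortexRegion-class] (or an M x 3 voxel index matrix).
#' @param vortVolume vorticity vector volume on the same grid (1/s).
#' @return list with `vortMax` and `vortMean` (1/s).
#' @export
vorticityStats <- function(region, vortVolume) {
  vox <- if (is(region, "VortexRegion")) region@voxels else region
  if (!nrow(vox)) stop("empty region: vorticity statistics undefined")
  mag <- sqrt(vortVolume[cbind(vox, 1L)]^2 +
                vortVolume[cbind(vox, 2L)]^2 +
                vortVolume[cbind(vox, 3L)]^2)
  list(vortMax = unname(stats::quantile(mag, 0.95, type = 7)),
       vortMean = mean(mag))
}

#' Region volume in mL
#'
#' Number of region voxels times the voxel volume.
#'
#' @param region a [VortexRegion-class] or voxel index matrix.
#' @param grid the [FlowGrid-class] (spacing in mm).
#' @export
regionVolume <- function(region, grid) {
  vox <- if (is(region, "VortexRegion")) region@voxels else region
  nrow(vox) * prod(grid@spacing) / 1000 # mm^3 -> mL
}

#' Kinetic energy of the ring region
#'
#' `ekinAbs = sum over region voxels of 1/2 rho |v|^2 * voxel volume`,
#' computed from the full (un-decomposed) velocity magnitude with a blood
#' density of rho = 1060 kg/m^3; reported in mJ. `ekinRel` is the
#' normalization by the region volume, in J/m^3.
#'
#' @param region a [VortexRegion-class] or voxel index matrix.
#' @param velFrame full velocity frame `c(dims, 3)` (m/s) on the same grid.
#' @param grid the [FlowGrid-class].
#' @param rho blood density in kg/m^3.
#' @return list with `ekinAbs` (mJ) and `ekinRel` (J/m^3).
#' @export
kineticEnergy <- function(region, velFrame, grid, rho = 1060) {
  vox <- if (is(region, "VortexRegion")) region@voxels else region
  if (!nrow(vox)) stop("empty region: kinetic energy undefined")
  v2 <- velFrame[cbind(vox, 1L)]^2 + velFrame[cbind(vox, 2L)]^2 +
    velFrame[cbind(vox, 3L)]^2
  voxVolM3 <- prod(grid@spacing) * 1e-9
  ekinJ <- sum(0.5 * rho * v2 * voxVolM3)
  volM3 <- nrow(vox) * voxVolM3
  list(ekinAbs = ekinJ * 1000, ekinRel = ekinJ / volM3)
}

#' Angle between the ring core plane and the LV long axis
#'
#' A plane is fitted to the core points by total least squares (the normal
#' is the direction of least variance); the reported angle is the angle
#' between the fitted plane and the long-axis direction, i.e. 90 degrees
#' minus the angle between the plane normal and the axis, folded into
#' \[0, 90\]. A ring lying in a short-axis plane (normal parallel to the long
#' axis) therefore has alpha = 90 degrees.
#'
#' @param core a [VortexCore-class] (or a P x 3 point matrix).
#' @param longAxis unit 3-vector.
#' @return angle in degrees, or `NA` for collinear cores.
#' @export
angleToLongAxis <- function(core, longAxis) {
  pts <- if (is(core, "VortexCore")) core@points else core
  if (is.null(dim(pts)) || nrow(pts) < 3L) return(NA_real_)
  X <- sweep(pts, 2, colMeans(pts), "-")
  sv <- svd(X, nu = 0)
  if (sv$d[2] <= 1e-9 * sv$d[1]) return(NA_real_) # collinear
  nrm <- sv$v[, 3]
  cosang <- abs(sum(nrm * longAxis)) / sqrt(sum(longAxis^2))
  angNormal <- acos(pmin(1, cosang)) * 180 / pi # in [0, 90]
  90 - angNormal
}

#' Circularity index of the ring core
#'
#' Ratio of the second-largest to the largest principal axis length of an
#' ellipsoid fitted to the core points ([ellipsoidAxes()]); 1 for a
#' perfectly circular ring. Clipped to \[0, 1\].
#'
#' @param core a [VortexCore-class] or point matrix.
#' @return circularity index, or `NA` when degenerate.
#' @export
circularityIndex <- function(core) {
  pts <- if (is(core, "VortexCore")) core@points else core
  ax <- tryCatch(ellipsoidAxes(pts), error = function(e) NULL)
  if (is.null(ax) || ax$major <= 0) return(NA_real_)
  min(1, max(0, ax$minor / ax$major))
}

#' Per-frame parameter table and E/A peak summaries
#'
#' Computes the six ring parameters in every frame with an MV-ring core and
#' region; other frames carry `present = FALSE` and missing values. Peak
#' summaries are the per-parameter maxima over the frames of each
#' membership period (E first, A second, in window order).
#'
#' @param cores per-frame list of [VortexCore-class] or `NULL`.
#' @param regions per-frame list of [VortexRegion-class] or `NULL`
#'   (full-grid voxel indices).
#' @param velocity the full [VelocitySeries-class].
#' @param longAxis unit 3-vector, LV long axis.
#' @param rho blood density (kg/m^3).
#' @return list with `params` (data.frame, one row per frame, columns
#'   `frame, present, vol_mL, vort_max_s1, vort_mean_s1, ekin_abs_mJ,
#'   ekin_rel_Jm3, alpha_deg, ci`) and `peaks` (per-period list of peak
#'   values).
#' @export
parameterTimecourse <- function(cores, regions, velocity, longAxis,
                                rho = 1060) {
  grid <- velocity@grid
  n <- grid@nFrames
  spacingM <- grid@spacing / 1000
  out <- data.frame(frame = seq_len(n), present = FALSE, vol_mL = NA_real_,
                    vort_max_s1 = NA_real_, vort_mean_s1 = NA_real_,
                    ekin_abs_mJ = NA_real_, ekin_rel_Jm3 = NA_real_,
                    alpha_deg = NA_real_, ci = NA_real_)
  for (i in seq_len(n)) {
    cl <- cores[[i]]; rg <- regions[[i]]
    if (is.null(cl) || is.null(rg) || !isTRUE(cl@isMVRing) ||
        !nrow(rg@voxels)) next
    vort <- vorticityField(velocity@frames[[i]], spacingM)
    vs <- vorticityStats(rg, vort)
    ke <- kineticEnergy(rg, velocity@frames[[i]], grid, rho = rho)
    out$present[i] <- TRUE
    out$vol_mL[i] <- regionVolume(rg, grid)
    out$vort_max_s1[i] <- vs$vortMax
    out$vort_mean_s1[i] <- vs$vortMean
    out$ekin_abs_mJ[i] <- ke$ekinAbs
    out$ekin_rel_Jm3[i] <- ke$ekinRel
    out$alpha_deg[i] <- angleToLongAxis(cl, longAxis)
    out$ci[i] <- circularityIndex(cl)
  }
  # membership periods: runs of present frames (cyclic order not unwrapped;
  # periods are contiguous within the E and A tracking ranges)
  r <- rle(out$present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  periods <- Map(function(s, e) s:e, starts[r$values], ends[r$values])
  cols <- c("vol_mL", "vort_max_s1", "vort_mean_s1", "ekin_abs_mJ",
            "ekin_rel_Jm3", "alpha_deg", "ci")
  peaks <- lapply(periods, function(fr) {
    pk <- vapply(cols, function(cn) suppressWarnings(
      max(out[[cn]][fr], na.rm = TRUE)), numeric(1))
    pk[!is.finite(pk)] <- NA_real_
    c(list(frames = fr), as.list(pk))
  })
  if (length(peaks) >= 1L)
    names(peaks) <- c("E", "A", paste0("extra", seq_len(max(0, length(peaks) - 2L))))[
      seq_along(peaks)]
  list(params = out, peaks = peaks)
}
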