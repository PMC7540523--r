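# Analytic vortex-ring flow phantoms: ground-truthed 4D velocity series that
# emulate transmitral vortex-ring formation (an E-wave and an A-wave ring
# with dissolution during diastasis), inside an ellipsoidal LV mask, with
# optional gradient-form contamination and Gaussian velocity noise.

#' Default acquisition-scale phantom grid
#'
#' 64 x 64 x 40 voxels at 1.8 x 2.5 x 4 mm spacing, 30 cardiac frames --
#' the spatial and temporal scale of a typical whole-heart 4D-flow
#' acquisition.
#'
#' @param nFrames number of cardiac frames.
#' @param frameDuration frame duration in ms.
#' @export
phantomGrid <- function(nFrames = 30L, frameDuration = 33) {
  FlowGrid(c(64L, 64L, 40L), spacing = c(1.8, 2.5, 4),
           origin = c(0, 0, 0), frameDuration = frameDuration,
           nFrames = nFrames)
}

# Gaussian (Lamb-Oseen-like) Biot-Savart smoothing factor for a filament
# with core radius a: sigma = a / sqrt(2), so the vorticity profile of a
# straight filament is Gamma / (pi a^2) * exp(-rho^2 / a^2).
.bsKernelFactor <- function(dist, coreRadius) {
  sigma <- coreRadius / sqrt(2)
  s <- dist / sigma
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  erf(s / sqrt(2)) - sqrt(2 / pi) * s * exp(-s^2 / 2)
}

# orthonormal basis completing a unit normal
.planeBasis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  rbind(e1, e2)
}

#' Velocity field of a regularized circular vortex filament
#'
#' Biot-Savart integration over a polygonal discretization of the ring
#' (default 128 segments) with Gaussian core regularization of radius
#' `coreRadius`; the field is analytically divergence-free. The circulation
#' is `amplitudeCurve[frame] * circulation`.
#'
#' @param spec a [RingSpec-class].
#' @param grid a [FlowGrid-class].
#' @param frame frame index (selects the amplitude).
#' @param nSegments polygon segments (>= 64).
#' @param points optional M x 3 matrix of physical positions (mm) to
#'   evaluate at instead of the full grid; then an M x 3 matrix is returned.
#' @return array `c(shape, 3)` of velocities in m/s (or an M x 3 matrix).
#' @export
ringVelocityField <- function(spec, grid, frame = 1L, nSegments = 128L,
                              points = NULL) {
  stopifnot(nSegments >= 64L)
  amp <- spec@amplitudeCurve[frame]
  onGrid <- is.null(points)
  if (onGrid) {
    xs <- grid@origin[1] + (seq_len(grid@shape[1]) - 1) * grid@spacing[1]
    ys <- grid@origin[2] + (seq_len(grid@shape[2]) - 1) * grid@spacing[2]
    zs <- grid@origin[3] + (seq_len(grid@shape[3]) - 1) * grid@spacing[3]
    points <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  }
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  M <- nrow(points)
  vel <- matrix(0, M, 3)
  if (amp > 0) {
    P <- points / 1000 # metres
    ctr <- spec@center / 1000
    R <- spec@radius / 1000
    a <- spec@coreRadius / 1000
    gam <- amp * spec@circulation
    B <- .planeBasis(spec@normal)
    th <- seq(0, 2 * pi, length.out = nSegments + 1L)
    ringp <- t(ctr + R * (outer(B[1, ], cos(th)) + outer(B[2, ], sin(th))))
    for (s in seq_len(nSegments)) {
      dl <- ringp[s + 1L, ] - ringp[s, ]
      mid <- (ringp[s + 1L, ] + ringp[s, ]) / 2
      rx <- P[, 1] - mid[1]; ry <- P[, 2] - mid[2]; rz <- P[, 3] - mid[3]
      d <- sqrt(rx^2 + ry^2 + rz^2)
      d[d < 1e-12] <- 1e-12
      g <- .bsKernelFactor(d, a)
      f <- gam / (4 * pi) * g / d^3
      vel[, 1] <- vel[, 1] + f * (dl[2] * rz - dl[3] * ry)
      vel[, 2] <- vel[, 2] + f * (dl[3] * rx - dl[1] * rz)
      vel[, 3] <- vel[, 3] + f * (dl[1] * ry - dl[2] * rx)
    }
  }
  if (onGrid) array(vel, c(grid@shape, 3L)) else vel
}

#' Analytic vorticity magnitude of the regularized ring
#'
#' For the Gaussian-core filament the vorticity profile (straight-filament
#' limit, accurate for `coreRadius << radius`) is
#' `Gamma / (pi a^2) * exp(-rho^2 / a^2)` with `rho` the distance to the
#' filament circle.
#'
#' @param spec a [RingSpec-class].
#' @param points M x 3 matrix of physical positions (mm).
#' @param frame frame index (selects the amplitude).
#' @return vorticity magnitudes in 1/s.
#' @export
ringVorticityMagnitude <- function(spec, points, frame = 1L) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  amp <- spec@amplitudeCurve[frame]
  t0 <- sweep(points, 2, spec@center, "-") / 1000
  ax <- drop(t0 %*% spec@normal)
  rad <- t0 - outer(ax, spec@normal)
  rr <- sqrt(rowSums(rad^2))
  a <- spec@coreRadius / 1000
  rho2 <- (rr - spec@radius / 1000)^2 + ax^2
  amp * spec@circulation / (pi * a^2) * exp(-rho2 / a^2)
}

#' Per-frame identical ellipsoidal LV mask
#'
#' A voxel belongs to the mask when its center lies inside the ellipsoid.
#'
#' @param grid a [FlowGrid-class].
#' @param center ellipsoid center (mm).
#' @param semiAxes numeric(3) semi-axes (mm), all > 0.
#' @param nFrames number of mask frames (defaults to the grid's).
#' @return a [MaskSeries-class] with provenance `"synthetic"`.
#' @export
ellipsoidLVMask <- function(grid, center, semiAxes, nFrames = grid@nFrames) {
  stopifnot(all(semiAxes > 0))
  lo <- grid@origin
  hi <- grid@origin + (grid@shape - 1) * grid@spacing
  if (any(center - semiAxes < lo - grid@spacing) ||
      any(center + semiAxes > hi + grid@spacing))
    stop("ellipsoid extends outside the grid")
  xs <- (grid@origin[1] + (seq_len(grid@shape[1]) - 1) * grid@spacing[1] -
           center[1]) / semiAxes[1]
  ys <- (grid@origin[2] + (seq_len(grid@shape[2]) - 1) * grid@spacing[2] -
           center[2]) / semiAxes[2]
  zs <- (grid@origin[3] + (seq_len(grid@shape[3]) - 1) * grid@spacing[3] -
           center[3]) / semiAxes[3]
  m <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") < 1
  if (!any(m)) stop("ellipsoid mask is empty (semi-axes below voxel spacing?)")
  g2 <- grid
  g2@nFrames <- as.integer(nFrames)
  MaskSeries(g2, rep(list(m), nFrames), provenance = "synthetic")
}

# smooth raised-sine ramp over a window of frames: positive on every window
# frame, zero outside
.windowAmplitude <- function(n, window, peak) {
  a <- numeric(n)
  L <- length(window)
  a[window] <- peak * sin(pi * seq_len(L) / (L + 1))
  a
}

#' Biphasic vortex-ring flow phantom
#'
#' Generates a ground-truthed 4D-flow phantom: a toroidal vortex ring inside
#' an ellipsoidal LV mask whose circulation follows a biphasic (E/A-wave
#' like) amplitude curve -- positive with smooth ramps inside the E and A
#' windows, exactly zero during diastasis and systole. Contamination is
#' added as `gradAmp` times the gradient of a smooth random scalar field
#' (rotation-free, so the true divergence-free part stays the clean ring
#' field) plus iid Gaussian velocity noise. The truth (core circles, region,
#' presence flags) is recorded before contamination.
#'
#' The defaults place a ring of radius 16 mm with a 4 mm Gaussian core at
#' the center of an ellipsoidal LV with semi-axes 22.5 x 22.5 x 42 mm
#' (lateral diameter 45 mm, base-apex length 84 mm), ring plane
#' perpendicular to the LV long axis (z), on the acquisition-scale grid of
#' [phantomGrid()]. The E-wave amplitude exceeds the A-wave amplitude, as in
#' normal diastolic filling.
#'
#' @param grid a [FlowGrid-class]; defaults to [phantomGrid()].
#' @param eaTiming list with integer frame windows `e` and `a`; they must be
#'   disjoint with a gap of at least 2 frames (diastasis).
#' @param amplitudes peak relative amplitudes of the E and A rings.
#' @param noiseSd Gaussian velocity noise sd in m/s.
#' @param gradAmp peak magnitude (m/s) of the gradient-form contamination.
#' @param seed RNG seed for noise and contamination.
#' @param radius,coreRadius,circulation ring geometry (mm, mm, m^2/s).
#' @param center ring center (mm); defaults to the grid center.
#' @param normal ring plane normal; defaults to the LV long axis (z).
#' @param maskSemiAxes LV ellipsoid semi-axes (mm).
#' @param nSegments Biot-Savart polygon segments.
#' @return list with `velocity` ([VelocitySeries-class]), `masks`
#'   ([MaskSeries-class]), `truth` ([PhantomTruth-class]) and `spec`
#'   ([RingSpec-class]).
#' @export
biphasicPhantom <- function(grid = phantomGrid(),
                            eaTiming = list(e = 3:8, a = 14:19),
                            amplitudes = c(e = 1, a = 0.6),
                            noiseSd = 0.02, gradAmp = 0.05, seed = 1L,
                            radius = 16, coreRadius = 4, circulation = 0.01,
                            center = NULL, normal = c(0, 0, 1),
                            maskSemiAxes = c(22.5, 22.5, 42),
                            nSegments = 128L) {
  e <- as.integer(eaTiming$e); a <- as.integer(eaTiming$a)
  if (length(intersect(e, a)))
    stop("E and A windows overlap")
  if (min(a) - max(e) - 1L < 2L && min(e) - max(a) - 1L < 2L)
    stop("E and A windows must be separated by a diastasis of >= 2 frames")
  n <- grid@nFrames
  if (any(c(e, a) < 1L) || any(c(e, a) > n)) stop("window frames out of range")
  if (is.null(center))
    center <- grid@origin + (grid@shape - 1) * grid@spacing / 2
  amp <- .windowAmplitude(n, e, amplitudes[["e"]]) +
    .windowAmplitude(n, a, amplitudes[["a"]])
  spec <- RingSpec(center = center, normal = normal, radius = radius,
                   coreRadius = coreRadius, circulation = circulation,
                   amplitudeCurve = amp)
  masks <- ellipsoidLVMask(grid, center, maskSemiAxes, nFrames = n)
  masks@provenance <- "synthetic"

  # base field at amplitude 1 (linear in amplitude: computed once)
  base <- ringVelocityField(
    RingSpec(center, normal, radius, coreRadius, circulation,
             amplitudeCurve = rep(1, n)), grid, frame = 1L,
    nSegments = nSegments)

  # truth region: Q > 0 of the clean field is invariant to positive
  # amplitude scaling, so one region serves all present frames
  qClean <- qField(base, grid@spacing / 1000)
  inMask <- masks@frames[[1]]
  pos <- qClean > 0 & inMask
  regionVox <- NULL
  if (any(pos)) {
    comps <- .connectedComponents26(which(pos), grid@shape)
    regionVox <- comps[[which.max(vapply(comps, nrow, integer(1)))]]
  }
  presence <- amp > 0
  truth <- new("PhantomTruth",
               coreCircles = lapply(seq_len(n), function(i) {
                 if (presence[i])
                   list(center = center, normal = spec@normal, radius = radius)
                 else NULL
               }),
               regionTruth = lapply(seq_len(n), function(i) {
                 if (presence[i]) regionVox else NULL
               }),
               presence = presence,
               longAxis = c(0, 0, 1))

  set.seed(seed)
  V <- prod(grid@shape)
  frames <- vector("list", n)
  # static smooth scalar field; its gradient emulates a residual
  # phase-offset (eddy-current-like) background, constant over the cycle
  if (gradAmp > 0) {
    phi <- array(stats::rnorm(V), grid@shape)
    phi <- .gaussSmooth3(phi, c(4, 4, 4))
    gphi <- array(0, c(grid@shape, 3L))
    for (ax in 1:3)
      gphi[, , , ax] <- .ddAxis(phi, ax, grid@spacing[ax] / 1000)
    gmax <- max(sqrt(gphi[, , , 1]^2 + gphi[, , , 2]^2 + gphi[, , , 3]^2))
    contam <- gphi * (gradAmp / gmax)
  } else {
    contam <- array(0, c(grid@shape, 3L))
  }
  for (i in seq_len(n)) {
    f <- amp[i] * base + contam
    if (noiseSd > 0)
      f <- f + array(stats::rnorm(3 * V, 0, noiseSd), c(grid@shape, 3L))
    frames[[i]] <- f
  }
  list(velocity = VelocitySeries(grid, frames, unitsIn = "m/s"),
       masks = masks, truth = truth, spec = spec)
}
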