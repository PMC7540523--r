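# Finite-difference primitives shared by the Hodge, Q and vorticity code.
# All stencils are second order: central in the interior, one-sided
# three-point at the two faces of each axis.

# partial derivative of a 3D scalar array along axis (1, 2 or 3);
# h is the spacing along that axis (any length unit; the result carries
# units of value / h-unit)
.ddAxis <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 3L) stop("need at least 3 samples along axis ", axis)
  idx <- function(k) {
    i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i[[axis]] <- k
    arr[i[[1]], i[[2]], i[[3]], drop = FALSE]
  }
  out <- array(0, d)
  asn <- function(k, val) {
    i <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i[[axis]] <- k
    out[i[[1]], i[[2]], i[[3]]] <<- val
  }
  asn(2:(n - 1L), (idx(3:n) - idx(1:(n - 2L))) / (2 * h))
  asn(1L, (-3 * idx(1L) + 4 * idx(2L) - idx(3L)) / (2 * h))
  asn(n, (3 * idx(n) - 4 * idx(n - 1L) + idx(n - 2L)) / (2 * h))
  out
}

#' Discrete curl of a vector volume
#'
#' Central differences in the interior, second-order one-sided stencils at
#' the volume faces; anisotropic spacing is respected. The same stencils are
#' used throughout the package (Hodge operator assembly, vorticity fields),
#' so `curl(psi)` from the solver is exactly reproducible with this function.
#'
#' @param field array of dim `c(nx, ny, nz, 3)`; a 3-component vector volume.
#' @param spacing numeric(3) voxel spacing. Units are the caller's: velocity
#'   in m/s with spacing in metres yields curl in 1/s.
#' @return array of the same shape: the curl.
#' @examples
#' # rigid rotation about z at 1 rad/s has curl (0, 0, 2)
#' n <- 9; h <- 0.01
#' x <- (0:(n - 1)) * h
#' g <- expand.grid(x = x, y = x, z = x)
#' v <- array(0, c(n, n, n, 3))
#' v[, , , 1] <- -g$y; v[, , , 2] <- g$x
#' w <- discreteCurl(v, c(h, h, h))
#' stopifnot(abs(w[5, 5, 5, 3] - 2) < 1e-12)
#' @export
discreteCurl <- function(field, spacing) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  u1 <- field[, , , 1]; u2 <- field[, , , 2]; u3 <- field[, , , 3]
  out <- array(0, dim(field))
  out[, , , 1] <- .ddAxis(u3, 2L, spacing[2]) - .ddAxis(u2, 3L, spacing[3])
  out[, , , 2] <- .ddAxis(u1, 3L, spacing[3]) - .ddAxis(u3, 1L, spacing[1])
  out[, , , 3] <- .ddAxis(u2, 1L, spacing[1]) - .ddAxis(u1, 2L, spacing[2])
  out
}

#' Discrete divergence of a vector volume
#'
#' Same stencils as [discreteCurl()].
#'
#' @inheritParams discreteCurl
#' @return scalar array of dim `c(nx, ny, nz)`.
#' @export
discreteDivergence <- function(field, spacing) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  .ddAxis(field[, , , 1], 1L, spacing[1]) +
    .ddAxis(field[, , , 2], 2L, spacing[2]) +
    .ddAxis(field[, , , 3], 3L, spacing[3])
}

#' Velocity gradient tensor field
#'
#' Returns the 3x3 velocity gradient \eqn{G_{ij} = \partial v_i / \partial
#' x_j} per voxel, computed with the package's finite-difference stencils.
#'
#' @inheritParams discreteCurl
#' @return array of dim `c(nx, ny, nz, 3, 3)`; last two dims index (i, j).
#' @export
velocityGradientTensor <- function(field, spacing) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  d <- dim(field)[1:3]
  out <- array(0, c(d, 3, 3))
  for (i in 1:3)
    for (j in 1:3)
      out[, , , i, j] <- .ddAxis(field[, , , i], j, spacing[j])
  out
}

# ---- trilinear interpolation ----------------------------------------------

# Vectorized trilinear interpolation of a 3D array at fractional 1-based
# voxel coordinates (M x 3 matrix). Points outside the grid return `outside`.
.interp3 <- function(arr, pts, outside = NA_real_) {
  d <- dim(arr)
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    is.finite(x) & is.finite(y) & is.finite(z)
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (x0 - 1) + (y0 - 1) * n1 + (z0 - 1) * n12 + 1
  v000 <- arr[base];            v100 <- arr[base + 1]
  v010 <- arr[base + n1];       v110 <- arr[base + 1 + n1]
  v001 <- arr[base + n12];      v101 <- arr[base + 1 + n12]
  v011 <- arr[base + n1 + n12]; v111 <- arr[base + 1 + n1 + n12]
  val <- v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) +
    v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz +
    v111 * fx * fy * fz
  out[ok] <- val
  out
}

# interpolate a 3-component field (dim c(d, 3)) at M x 3 fractional voxel
# coordinates; returns M x 3
.interp3v <- function(field, pts, outside = NA_real_) {
  cbind(.interp3(field[, , , 1], pts, outside),
        .interp3(field[, , , 2], pts, outside),
        .interp3(field[, , , 3], pts, outside))
}
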