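# Helmholtz-Hodge extraction of the divergence-free velocity component.
#
# The divergence-free part r of a velocity field v is represented as the
# curl of a vector potential psi, which satisfies the curl-curl system
#   curl(curl(psi)) = curl(v),  psi = 0 on the box boundary shell.
# The discrete operator is rank deficient (discrete gradients lie in its
# null space), so the system is solved by minimum-norm least squares:
# LSQR started from zero, which converges to the minimum-norm solution.

# 1D differentiation matrix: central interior, second-order one-sided ends.
# Identical stencils to .ddAxis(), so matrix and array paths agree exactly.
.dmat1d <- function(n, h) {
  k <- 2:(n - 1L)
  i <- c(k, k, 1L, 1L, 1L, n, n, n)
  j <- c(k - 1L, k + 1L, 1L, 2L, 3L, n, n - 1L, n - 2L)
  x <- c(rep(-1, n - 2L), rep(1, n - 2L), -3, 4, -1, 3, -4, 1) / (2 * h)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

# sparse discrete curl operator on an nx x ny x nz box (3V x 3V), acting on
# fields flattened component-major: c(u1, u2, u3), x fastest within each
.curlMatrix <- function(dims, spacing) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  Ix <- Matrix::Diagonal(nx); Iy <- Matrix::Diagonal(ny)
  Iz <- Matrix::Diagonal(nz)
  Dx <- Matrix::kronecker(Iz, Matrix::kronecker(Iy, .dmat1d(nx, spacing[1])))
  Dy <- Matrix::kronecker(Iz, Matrix::kronecker(.dmat1d(ny, spacing[2]), Ix))
  Dz <- Matrix::kronecker(.dmat1d(nz, spacing[3]), Matrix::kronecker(Iy, Ix))
  V <- nx * ny * nz
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(V, V))
  rbind(cbind(Z, -Dz, Dy),
        cbind(Dz, Z, -Dx),
        cbind(-Dy, Dx, Z))
}

#' Assemble the curl-curl operator for a box
#'
#' Builds the sparse discrete curl matrix `C` on the box and the curl-curl
#' system matrix `A = C C` with the boundary clamp applied (columns of all
#' three potential components on the one-voxel-thick boundary shell removed,
#' enforcing `psi = 0` there). The operator depends only on the box
#' dimensions and spacing, so it can be assembled once and reused across
#' cardiac frames.
#'
#' @param dims integer(3), box dimensions (each >= 3).
#' @param spacing numeric(3), voxel spacing (metres for SI output).
#' @return list with `C` (3V x 3V curl), `A` (clamped curl-curl), `At`
#'   (its transpose), `interior` (retained column indices) and `dims`.
#' @export
hodgeOperator <- function(dims, spacing) {
  stopifnot(all(dims >= 3L))
  C <- .curlMatrix(dims, spacing)
  A <- C %*% C
  bnd <- array(FALSE, dims)
  bnd[c(1L, dims[1]), , ] <- TRUE
  bnd[, c(1L, dims[2]), ] <- TRUE
  bnd[, , c(1L, dims[3])] <- TRUE
  interior <- which(rep(!bnd, 3L))
  A <- A[, interior, drop = FALSE]
  list(C = C, A = A, At = Matrix::t(A), interior = interior, dims = dims)
}

# LSQR (Paige & Saunders), damp = 0, started from zero so the limit is the
# minimum-norm least-squares solution. Stops when either the relative
# residual (consistent systems) or the normal-equation optimality measure
# ||A'r|| / (||A|| ||r||) (inconsistent systems) drops below tol.
.lsqr <- function(A, At, b, tol = 1e-8, maxIter = 10000L) {
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(list(x = numeric(ncol(A)), iterations = 0L, relres = 0,
                optres = 0, converged = TRUE))
  beta <- bnorm; u <- b / beta
  v <- as.numeric(At %*% u); alpha <- sqrt(sum(v^2))
  if (alpha == 0)
    return(list(x = numeric(ncol(A)), iterations = 0L, relres = 1,
                optres = 0, converged = TRUE))
  v <- v / alpha
  w <- v; x <- numeric(ncol(A))
  phibar <- beta; rhobar <- alpha
  Anorm <- 0
  test1 <- 1; test2 <- 1; itn <- 0L; converged <- FALSE
  while (itn < maxIter) {
    itn <- itn + 1L
    u <- as.numeric(A %*% v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    Anorm <- sqrt(Anorm^2 + alpha^2 + beta^2)
    v <- as.numeric(At %*% u) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha; rhobar <- -cs * alpha
    phi <- cs * phibar; phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    rnorm <- phibar
    arnorm <- alpha * abs(sn * phi)
    xnorm <- sqrt(sum(x^2))
    test1 <- rnorm / bnorm
    test2 <- if (rnorm > 0 && Anorm > 0) arnorm / (Anorm * rnorm) else 0
    if (test1 <= tol + tol * Anorm * xnorm / bnorm || test2 <= tol) {
      converged <- TRUE
      break
    }
  }
  list(x = x, iterations = itn, relres = test1, optres = test2,
       converged = converged)
}

#' Solve the vector-potential curl-curl system on a box
#'
#' Computes the vector potential `psi` with `curl(curl(psi)) = curl(field)`
#' and `psi = 0` clamped on the box boundary shell, by minimum-norm least
#' squares (LSQR from zero), and returns `psi` together with the
#' divergence-free field `r`, the discrete curl of `psi`.
#'
#' For fields that are exact discrete curls the reported residual is the
#' relative residual of the curl-curl system; for general (e.g. noisy)
#' fields the system is inconsistent and convergence is declared on the
#' least-squares optimality measure instead.
#'
#' @param field vector volume on the box, dim `c(dims, 3)` (m/s).
#' @param spacing numeric(3) voxel spacing in metres.
#' @param tol relative tolerance of the iterative solver.
#' @param maxIter iteration cap; defaults to 10 unknowns per-axis capped at
#'   `10 * number of unknowns`.
#' @param operator optional precomputed [hodgeOperator()] for these dims,
#'   reused across frames.
#' @return a [HodgeSolution-class].
#' @export
solveVectorPotential <- function(field, spacing, tol = 1e-8, maxIter = NULL,
                                 operator = NULL) {
  d <- dim(field)
  stopifnot(length(d) == 4L, d[4] == 3L)
  dims <- d[1:3]
  if (any(dims < 3L)) stop("box interior needs at least 3 voxels per axis")
  if (is.null(operator)) operator <- hodgeOperator(dims, spacing)
  stopifnot(identical(operator$dims, dims))
  nunk <- length(operator$interior)
  if (is.null(maxIter)) maxIter <- min(10L * nunk, 50000L)
  b <- as.numeric(operator$C %*% as.numeric(field))
  sol <- .lsqr(operator$A, operator$At, b, tol = tol, maxIter = maxIter)
  if (!sol$converged)
    stop(sprintf(paste("curl-curl solve did not converge in %d iterations;",
                       "achieved relative residual %.3g (optimality %.3g)"),
                 sol$iterations, sol$relres, sol$optres))
  psi <- numeric(3L * prod(dims))
  psi[operator$interior] <- sol$x
  r <- as.numeric(operator$C %*% psi)
  new("HodgeSolution",
      psi = array(psi, c(dims, 3L)),
      r = array(r, c(dims, 3L)),
      residual = min(sol$relres, sol$optres),
      iterations = as.integer(sol$iterations))
}

#' Divergence-free part of a velocity series on the LV bounding box
#'
#' Applies [solveVectorPotential()] frame by frame to the velocity field
#' restricted to `box`. The output field is tangential to the box faces by
#' construction (`psi = 0` on the boundary implies a vanishing normal curl
#' component up to discretization).
#'
#' @param series a [VelocitySeries-class].
#' @param box a [BoundingBox-class] inside the series grid.
#' @param tol relative solver tolerance.
#' @param maxIter optional iteration cap passed to [solveVectorPotential()].
#' @param verbose print per-frame solver statistics.
#' @return a [VelocitySeries-class] restricted to the box (cropped grid)
#'   holding the divergence-free fields; per-frame residuals and iteration
#'   counts are attached as attributes `hodgeResiduals` and
#'   `hodgeIterations`.
#' @export
divergenceFreePart <- function(series, box, tol = 1e-8, maxIter = NULL,
                               verbose = FALSE) {
  grid <- series@grid
  if (any(box@upper > grid@shape))
    stop("bounding box exceeds the grid")
  cg <- cropGrid(grid, box)
  spacingM <- cg@spacing / 1000
  op <- hodgeOperator(cg@shape, spacingM)
  res <- numeric(grid@nFrames)
  itn <- integer(grid@nFrames)
  frames <- vector("list", grid@nFrames)
  for (i in seq_len(grid@nFrames)) {
    f <- .cropArray(series@frames[[i]], box)
    hs <- solveVectorPotential(f, spacingM, tol = tol, maxIter = maxIter,
                               operator = op)
    frames[[i]] <- hs@r
    res[i] <- hs@residual
    itn[i] <- hs@iterations
    if (verbose)
      message(sprintf("frame %d: %d LSQR iterations, residual %.3g",
                      i, hs@iterations, hs@residual))
  }
  out <- VelocitySeries(cg, frames, unitsIn = "m/s")
  attr(out, "hodgeResiduals") <- res
  attr(out, "hodgeIterations") <- itn
  out
}
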