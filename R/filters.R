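# Separable Gaussian and median filtering used by the Q pipeline and the
# phantom generator.

.gaussKernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along `axis` of a 3D array with reflection padding
.convAxisReflect <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr * k)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  # reflected index sequence of length n + 2r
  idx <- c(rev(seq_len(min(r, n - 1L)) + 1L), seq_len(n),
           n - seq_len(min(r, n - 1L)))
  if (length(idx) < n + 2L * r) { # very small n relative to kernel
    while (length(idx) < n + 2L * r) idx <- c(idx[1], idx, idx[length(idx)])
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * mp[(t - 1L) + seq_len(n), , drop = FALSE]
  res <- array(out, da)
  aperm(res, order(perm))
}

# separable 3D Gaussian, sigma in voxels per axis
.gaussSmooth3 <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3)
    if (sigma[ax] > 0)
      arr <- .convAxisReflect(arr, .gaussKernel1d(sigma[ax]), ax)
  arr
}

# cubic median filter via the compiled kernel; window is an odd edge length
.medianFilter3 <- function(arr, size = 3L) {
  if (size <= 1L) return(arr)
  if (size %% 2L == 0L) stop("median window must be odd")
  out <- median_filter3_cpp(arr, dim(arr), as.integer(size))
  array(out, dim(arr))
}

# per-voxel Gaussian smoothing along the frame axis with cyclic boundary;
# frames: list of equally shaped arrays
.temporalGaussCyclic <- function(frames, sigma) {
  n <- length(frames)
  if (sigma <= 0 || n == 1L) return(frames)
  k <- .gaussKernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- array(0, dim(frames[[1]]))
    for (t in (-r):r) {
      j <- ((i - 1L + t) %% n) + 1L
      acc <- acc + k[t + r + 1L] * frames[[j]]
    }
    out[[i]] <- acc
  }
  out
}
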