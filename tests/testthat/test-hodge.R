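test_that("discrete curl reproduces hand-differentiated fields", {
  g <- isoGrid(12, 2)
  # uniform field: zero curl
  u <- array(0.3, c(g@shape, 3L))
  expect_equal(max(abs(discreteCurl(u, g@spacing / 1000))), 0)
  # rigid rotation about z at 1 rad/s: curl (0, 0, 2) everywhere (exact for
  # linear fields, including the one-sided face stencils)
  v <- rigidRotation(g, omega = 1)
  w <- discreteCurl(v, g@spacing / 1000)
  expect_equal(max(abs(w[, , , 1])), 0, tolerance = 1e-12)
  expect_equal(max(abs(w[, , , 2])), 0, tolerance = 1e-12)
  expect_equal(range(w[, , , 3]), c(2, 2), tolerance = 1e-12)
  # gradient of x^2 + y^2: curl vanishes to machine precision in the
  # interior (central differences are exact on quadratics)
  gq <- fieldFromFun(g, function(P) cbind(2 * P[, 1], 2 * P[, 2], 0))
  wq <- discreteCurl(gq, g@spacing)
  rng <- 2:11
  expect_lt(max(abs(wq[rng, rng, rng, ])), 1e-12)
})

test_that("discrete divergence is exact for linear fields", {
  g <- isoGrid(10, 2.5)
  # v = (x, y, z): divergence 3 (units of 1/length in the spacing unit)
  v <- fieldFromFun(g, function(P) P)
  dv <- discreteDivergence(v, g@spacing)
  expect_equal(range(dv), c(3, 3), tolerance = 1e-12)
  expect_equal(max(abs(discreteDivergence(rigidRotation(g), g@spacing))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(discreteDivergence(array(1, c(g@shape, 3L)),
                                          g@spacing))), 0)
})

test_that("curl-curl solve reconstructs a field that is a known curl", {
  # field built as the discrete curl of a compactly supported potential:
  # the solver must reproduce it almost exactly
  n <- 16L
  g <- isoGrid(n, 2)
  sp <- g@spacing / 1000
  ctr <- g@origin + (g@shape - 1) * g@spacing / 2
  bump <- fieldFromFun(g, function(P) {
    d2 <- rowSums(sweep(P, 2, ctr, "-")^2)
    w <- exp(-d2 / (2 * 3^2)) * 1e-3 # decayed to ~1e-11 at the box faces
    cbind(w, 2 * w, -w)
  })
  v0 <- discreteCurl(bump, sp)
  hs <- solveVectorPotential(v0, sp, tol = 1e-8)
  expect_lt(sqrt(sum((hs@r - v0)^2) / sum(v0^2)), 1e-3)
  expect_lt(hs@residual, 1e-5)
  # returned r is exactly the discrete curl of the returned psi
  expect_equal(hs@r, discreteCurl(hs@psi, sp), tolerance = 1e-12)
})

test_that("gradient fields are rejected by the projection", {
  n <- 16L
  g <- isoGrid(n, 2)
  sp <- g@spacing / 1000
  ctr <- g@origin + (g@shape - 1) * g@spacing / 2
  # discrete gradient of a smooth scalar vanishing near the faces (the
  # same construction the phantom generator uses for its contamination)
  phi <- fieldFromFun(g, function(P) {
    d2 <- rowSums(sweep(P, 2, ctr, "-")^2)
    cbind(exp(-d2 / (2 * 4^2)), 0, 0)
  })[, , , 1]
  gv <- array(0, c(g@shape, 3L))
  for (ax in 1:3) gv[, , , ax] <- mvring:::.ddAxis(phi, ax, sp[ax])
  hs <- solveVectorPotential(gv, sp, tol = 1e-8)
  expect_lt(sqrt(sum(hs@r^2) / sum(gv^2)), 1e-2)
})

test_that("iterative solution matches the dense minimum-norm oracle on 5^3", {
  dims <- c(5L, 5L, 5L)
  sp <- c(1.8, 2.5, 4) / 1000
  op <- hodgeOperator(dims, sp)
  set.seed(7)
  vf <- array(rnorm(3 * prod(dims), 0, 0.1), c(dims, 3L))
  b <- as.numeric(op$C %*% as.numeric(vf))
  # dense oracle: SVD pseudo-inverse (minimum-norm least squares)
  Ad <- as.matrix(op$A)
  sv <- svd(Ad)
  keep <- sv$d > max(dim(Ad)) * max(sv$d) * .Machine$double.eps
  xd <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% b) / sv$d[keep])
  hs <- solveVectorPotential(vf, sp, tol = 1e-12, operator = op)
  psiIter <- as.numeric(hs@psi)[op$interior]
  expect_lt(sqrt(sum((psiIter - xd)^2) / sum(xd^2)), 1e-8)
  psiD <- numeric(3 * prod(dims)); psiD[op$interior] <- xd
  rD <- as.numeric(op$C %*% psiD)
  expect_lt(sqrt(sum((as.numeric(hs@r) - rD)^2) / sum(rD^2)), 1e-8)
})

test_that("projection is tangential, divergence-free and linear", {
  n <- 14L
  g <- isoGrid(n, 2, nFrames = 1L)
  sp <- g@spacing / 1000
  ctr <- g@origin + (g@shape - 1) * g@spacing / 2
  mkbump <- function(a1, a2, a3, s) fieldFromFun(g, function(P) {
    d2 <- rowSums(sweep(P, 2, ctr, "-")^2)
    w <- exp(-d2 / (2 * s^2)) * 1e-3
    cbind(a1 * w, a2 * w, a3 * w)
  })
  u <- discreteCurl(mkbump(1, -1, 2, 5), sp)
  v <- discreteCurl(mkbump(-2, 1, 1, 4), sp)
  pu <- solveVectorPotential(u, sp, tol = 1e-9)@r
  pv <- solveVectorPotential(v, sp, tol = 1e-9)@r
  # tangency: normal component on each box face is essentially zero
  rmax <- max(abs(pu))
  expect_lt(max(abs(pu[c(1, n), , , 1])), 1e-8 * rmax)
  expect_lt(max(abs(pu[, c(1, n), , 2])), 1e-8 * rmax)
  expect_lt(max(abs(pu[, , c(1, n), 3])), 1e-8 * rmax)
  # interior divergence of r is at the solver-tolerance level
  dv <- discreteDivergence(pu, sp)
  expect_lt(max(abs(dv[3:(n - 2), 3:(n - 2), 3:(n - 2)])),
            1e-6 * rmax / min(sp))
  # linearity of the projection
  puv <- solveVectorPotential(2 * u - 3 * v, sp, tol = 1e-9)@r
  expect_lt(sqrt(sum((puv - (2 * pu - 3 * pv))^2) / sum(puv^2)), 1e-6)
  # idempotence: projecting the projection changes little
  pp <- solveVectorPotential(pu, sp, tol = 1e-9)@r
  expect_lt(sqrt(sum((pp - pu)^2) / sum(pu^2)), 1e-3)
})

test_that("the solver reports non-convergence with the achieved residual", {
  g <- isoGrid(8, 2)
  set.seed(1)
  vf <- array(rnorm(3 * 8^3), c(g@shape, 3L))
  expect_error(solveVectorPotential(vf, g@spacing / 1000, tol = 1e-12,
                                    maxIter = 3L),
               "did not converge.*residual")
})

test_that("divergence-free series recovers the phantom from contamination", {
  # ring + gradient contamination on a grid large enough that the ring
  # field has decayed at the faces (the removed harmonic component is then
  # negligible in the interior)
  n <- 44L
  g <- FlowGrid(rep(n, 3L), spacing = rep(3, 3), nFrames = 1L)
  ctr <- g@origin + (g@shape - 1) * g@spacing / 2
  spec <- RingSpec(center = ctr, normal = c(0, 0, 1), radius = 8,
                   coreRadius = 5, circulation = 0.006,
                   amplitudeCurve = 1)
  clean <- ringVelocityField(spec, g, frame = 1L)
  phi <- fieldFromFun(g, function(P) {
    d2 <- rowSums(sweep(P, 2, ctr, "-")^2)
    cbind(exp(-d2 / (2 * 20^2)), 0, 0)
  })[, , , 1]
  grad <- array(0, c(g@shape, 3L))
  for (ax in 1:3)
    grad[, , , ax] <- mvring:::.ddAxis(phi, ax, g@spacing[ax] / 1000)
  gmax <- max(sqrt(grad[, , , 1]^2 + grad[, , , 2]^2 + grad[, , , 3]^2))
  grad <- grad * (0.05 / gmax)
  series <- VelocitySeries(g, list(clean + grad))
  box <- BoundingBox(c(0, 0, 0), rep(n, 3))
  rs <- divergenceFreePart(series, box, tol = 1e-7)
  rng <- 4:(n - 3)
  err <- sqrt(sum((rs@frames[[1]][rng, rng, rng, ] -
                     clean[rng, rng, rng, ])^2) /
                sum(clean[rng, rng, rng, ]^2))
  expect_lt(err, 0.05)
  # zero field maps to zero
  z <- VelocitySeries(FlowGrid(c(8, 8, 8), c(2, 2, 2), nFrames = 1L),
                      list(array(0, c(8, 8, 8, 3))))
  rz <- divergenceFreePart(z, BoundingBox(c(0, 0, 0), c(8, 8, 8)))
  expect_true(all(rz@frames[[1]] == 0))
})
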