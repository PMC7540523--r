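# A well-resolved analytic ring on an isotropic grid serves as the tracing
# fixture (Q and vorticity computed directly from the clean field).
ringTraceFixture <- function(maskHalf = FALSE) {
  fx <- ringFixture(n = 32L, h = 2, R = 10, a = 4, gamma = 0.008)
  spm <- fx$grid@spacing / 1000
  q <- qField(fx$field, spm)
  vort <- discreteCurl(fx$field, spm)
  if (maskHalf) {
    # remove one half-space: leaves an open half-ring of positive Q
    half <- seq_len(fx$grid@shape[1]) >
      (fx$grid@shape[1] / 2 + fx$spec@radius / 4)
    q[half, , ] <- -abs(q[half, , ]) - 1e-6
  }
  c(fx, list(q = q, vort = vort))
}

test_that("the predictor-corrector closes on the phantom ring", {
  fx <- ringTraceFixture()
  cfg <- traceConfig(fx$grid)
  seedIdx <- arrayInd(which.max(fx$q), dim(fx$q))
  seed <- drop(voxelToPhysical(fx$grid, seedIdx))
  cl <- traceCore(fx$q, fx$vort, seed, fx$grid, cfg)
  expect_true(cl@closed)
  expect_identical(classifyShape(cl, cfg), "torus")
  pts <- corePoints(cl)
  # mean distance to the true circle below the voxel spacing
  t0 <- sweep(pts, 2, fx$spec@center, "-")
  ax <- drop(t0 %*% fx$spec@normal)
  rr <- sqrt(rowSums((t0 - outer(ax, fx$spec@normal))^2))
  dist <- sqrt((rr - fx$spec@radius)^2 + ax^2)
  expect_lt(mean(dist), max(fx$grid@spacing))
  # circumference within 15% of 2 pi R
  len <- sum(sqrt(rowSums(diff(rbind(pts, pts[1, ]))^2)))
  expect_lt(abs(len - 2 * pi * fx$spec@radius) / (2 * pi * fx$spec@radius),
            0.15)
  # every core point carries positive interpolated Q
  qAt <- mvring:::.interp3(fx$q, physicalToVoxel(fx$grid, pts), outside = -1)
  expect_true(all(qAt > 0))
  # consecutive point spacing bounded by twice the step
  expect_lte(max(sqrt(rowSums(diff(pts)^2))), 2 * cfg@step + 1e-9)
  # determinism
  cl2 <- traceCore(fx$q, fx$vort, seed, fx$grid, cfg)
  expect_identical(corePoints(cl2), pts)
})

test_that("tracing rejects seeds outside the vortex", {
  fx <- ringTraceFixture()
  cfg <- traceConfig(fx$grid)
  corner <- drop(voxelToPhysical(fx$grid, c(2, 2, 2)))
  expect_error(traceCore(fx$q, fx$vort, corner, fx$grid, cfg),
               "seed outside vortex")
})

test_that("a masked half-ring yields an open trace ending at Q <= 0", {
  fx <- ringTraceFixture(maskHalf = TRUE)
  cfg <- traceConfig(fx$grid)
  seedIdx <- arrayInd(which.max(fx$q), dim(fx$q))
  seed <- drop(voxelToPhysical(fx$grid, seedIdx))
  cl <- traceCore(fx$q, fx$vort, seed, fx$grid, cfg)
  expect_false(cl@closed)
  pts <- corePoints(cl)
  expect_gt(nrow(pts), 10)
  # both open ends sit at the Q <= 0 frontier: stepping further along the
  # local tangent leaves the vortex
  qnear <- function(p, dirv) mvring:::.interp3(
    fx$q, physicalToVoxel(fx$grid, matrix(p + 2 * dirv, 1, 3)), outside = -1)
  d1 <- pts[1, ] - pts[2, ]
  d2 <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
  expect_lt(qnear(pts[1, ], d1 / sqrt(sum(d1^2))), max(fx$q) * 0.01)
  expect_lt(qnear(pts[nrow(pts), ], d2 / sqrt(sum(d2^2))), max(fx$q) * 0.01)
})

test_that("shape classification distinguishes torus, U and none", {
  g <- isoGrid(16, 2)
  cfg <- traceConfig(g)
  mkCore <- function(pts, closed) new(
    "VortexCore", points = pts, shape = "none", closed = closed,
    frame = 1L, isMVRing = FALSE, majorAxis = 1, minorAxis = 1,
    centroid = colMeans(pts))
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  circle <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_identical(classifyShape(mkCore(circle, TRUE), cfg), "torus")
  # semicircle: 180 degrees of turning >= the 150 degree U threshold
  th2 <- seq(0, pi, length.out = 20)
  semi <- cbind(10 * cos(th2), 10 * sin(th2), 0)
  expect_identical(classifyShape(mkCore(semi, FALSE), cfg), "U")
  straight <- cbind(seq(0, 20, length.out = 10), 0, 0)
  expect_identical(classifyShape(mkCore(straight, FALSE), cfg), "none")
  # two quarter-arcs with adjacent endpoints: jointly a bracket
  th3 <- seq(0, pi * 0.9, length.out = 15)
  a1 <- cbind(10 * cos(th3), 10 * sin(th3), 0)
  a2 <- cbind(10 * cos(th3 + pi), 10 * sin(th3 + pi), 0)
  expect_identical(classifyShape(list(mkCore(a1, FALSE), mkCore(a2, FALSE)),
                                 cfg), "bracket")
  # far-apart open lines are not a bracket
  a3 <- a2; a3[, 3] <- a3[, 3] + 50
  expect_identical(classifyShape(list(mkCore(a1, FALSE), mkCore(a3, FALSE)),
                                 cfg), "none")
})

test_that("ellipsoid axes recover circle and ellipse dimensions", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circle <- cbind(12 * cos(th), 12 * sin(th), 0)
  ax <- ellipsoidAxes(circle)
  expect_equal(ax$major, 24, tolerance = 0.02)
  expect_equal(ax$minor, 24, tolerance = 0.02)
  ell <- cbind(20 * cos(th), 10 * sin(th), 0)
  axe <- ellipsoidAxes(ell)
  expect_equal(axe$major, 40, tolerance = 0.02)
  expect_equal(axe$minor, 20, tolerance = 0.02)
  expect_error(ellipsoidAxes(cbind(1:5, 1:5, 1:5)), "collinear")
  expect_error(ellipsoidAxes(circle[1:2, ]), "3 core points")
})

test_that("membership tracking breaks when the ring teleports", {
  # four frames of an analytic ring; after frame 1 the ring is displaced by
  # 30 mm, beyond the default 10 mm tracking distance. Tracking proceeds
  # from both peak frames (1 and 4), so the jump is visible to the
  # E-forward chain at frame 2
  n <- 40L
  g <- FlowGrid(c(n, n, 24L), spacing = c(2, 2, 2), nFrames = 4L)
  ctrA <- c(24, 39, 23)
  ctrB <- ctrA + c(30, 0, 0)
  mkQ <- function(ctr) {
    spec <- RingSpec(ctr, c(0, 0, 1), 8, 3, 0.008, 1)
    f <- ringVelocityField(spec, g)
    spm <- g@spacing / 1000
    list(q = qField(f, spm), vort = discreteCurl(f, spm))
  }
  A <- mkQ(ctrA); B <- mkQ(ctrB)
  qFrames <- list(A$q, B$q, B$q, B$q)
  vorts <- list(A$vort, B$vort, B$vort, B$vort)
  masks <- rep(list(array(TRUE, g@shape)), 4)
  ft <- frameThresholds(qFrames, masks)
  qs <- new("QSeries", grid = g, box = BoundingBox(c(0, 0, 0), g@shape),
            qFrames = qFrames, thresholds = ft$thresholds,
            maxCurve = ft$maxCurve, maxLocations = ft$maxLocations,
            vortexFrames = 1:4, peakFrames = c(1L, 4L))
  cands <- lapply(1:4, function(f) {
    regs <- thresholdRegions(qFrames[[f]], ft$thresholds[f] * 0.5, 5L)
    lapply(regs, function(vx) new("VortexCandidate", voxels = vx,
                                  fc = 1, dMax = 1,
                                  centroid = colMeans(voxelToPhysical(g, vx)),
                                  frame = f))
  })
  cfg <- traceConfig(g)
  cores <- trackCores(cands, qs, vorts, cfg)
  flags <- vapply(cores, function(cl) !is.null(cl) && isTRUE(cl@isMVRing),
                  logical(1))
  # peaks are seeded as rings; the jump breaks the E-forward chain
  expect_true(flags[1])
  expect_true(flags[4])
  expect_false(flags[2])
  # with a permissive tracking distance the chain holds everywhere
  cfg2 <- traceConfig(g, trackDist = 100)
  flags2 <- vapply(trackCores(cands, qs, vorts, cfg2),
                   function(cl) !is.null(cl) && isTRUE(cl@isMVRing),
                   logical(1))
  expect_true(all(flags2))
})
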