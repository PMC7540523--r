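test_that("gradient tensor matches hand differentiation", {
  g <- isoGrid(10, 2)
  spm <- g@spacing / 1000
  expect_equal(max(abs(velocityGradientTensor(array(2, c(g@shape, 3L)),
                                              spm))), 0)
  # shear v = (gamma * y, 0, 0): only entry (1, 2) is gamma
  gam <- 0.7
  sh <- fieldFromFun(g, function(P) cbind(gam * P[, 2] / 1000, 0, 0))
  G <- velocityGradientTensor(sh, spm)
  expect_equal(range(G[, , , 1, 2]), c(gam, gam), tolerance = 1e-12)
  G[, , , 1, 2] <- 0
  expect_lt(max(abs(G)), 1e-12)
  # rigid rotation: antisymmetric with (1,2) = -omega, (2,1) = omega
  Gr <- velocityGradientTensor(rigidRotation(g, 1.5), spm)
  expect_equal(range(Gr[, , , 1, 2]), c(-1.5, -1.5), tolerance = 1e-12)
  expect_equal(range(Gr[, , , 2, 1]), c(1.5, 1.5), tolerance = 1e-12)
})

test_that("Q is omega^2 for rigid rotation, zero for shear and uniform flow", {
  g <- isoGrid(12, 2)
  spm <- g@spacing / 1000
  omega <- 2.3
  q <- qField(rigidRotation(g, omega), spm)
  expect_lt(max(abs(q - omega^2)) / omega^2, 1e-10)
  qs <- qField(fieldFromFun(g, function(P) cbind(0.4 * P[, 2] / 1000, 0, 0)),
               spm)
  expect_lt(max(abs(qs)), 1e-12)
  expect_equal(max(abs(qField(array(0.7, c(g@shape, 3L)), spm))), 0)
})

test_that("Q is Galilean invariant", {
  fx <- ringFixture(n = 20L, h = 2.5)
  spm <- fx$grid@spacing / 1000
  q1 <- qField(fx$field, spm)
  shifted <- fx$field
  shifted[, , , 1] <- shifted[, , , 1] + 0.37
  shifted[, , , 2] <- shifted[, , , 2] - 1.4
  shifted[, , , 3] <- shifted[, , , 3] + 0.02
  q2 <- qField(shifted, spm)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("Q filtering: constants unchanged, impulses removed, short-lived
           structures attenuated", {
  d <- c(9, 9, 9)
  const <- array(3.7, d)
  out <- smoothQSeries(list(const), 1, 3L, 1)
  expect_equal(out[[1]], const, tolerance = 1e-12)
  # single-voxel impulse dies in the median stage
  imp <- array(0, d); imp[5, 5, 5] <- 100
  med <- smoothQSeries(list(imp), 0, 3L, 0)[[1]]
  expect_equal(max(abs(med)), 0)
  # a structure present in 1 of 30 frames is attenuated >= 2x more than one
  # present in 5 consecutive frames (peak value after temporal smoothing)
  n <- 30L
  blip <- lapply(seq_len(n), function(i) {
    a <- array(0, d); if (i == 15) a[5, 5, 5] <- 1; a
  })
  sustained <- lapply(seq_len(n), function(i) {
    a <- array(0, d); if (i %in% 13:17) a[5, 5, 5] <- 1; a
  })
  pk1 <- max(vapply(smoothQSeries(blip, 0, 1L, 1),
                    function(a) a[5, 5, 5], numeric(1)))
  pk5 <- max(vapply(smoothQSeries(sustained, 0, 1L, 1),
                    function(a) a[5, 5, 5], numeric(1)))
  expect_gt(pk5 / pk1, 2)
})

test_that("temporal smoothing is cyclic across the cardiac cycle boundary", {
  d <- c(5, 5, 5)
  n <- 10L
  frames <- lapply(seq_len(n), function(i) {
    a <- array(0, d); if (i == 1) a[3, 3, 3] <- 1; a
  })
  sm <- smoothQSeries(frames, 0, 1L, 1)
  # frame n receives the same leakage as frame 2 (cyclic neighbour)
  expect_equal(sm[[n]][3, 3, 3], sm[[2]][3, 3, 3], tolerance = 1e-12)
  expect_gt(sm[[n]][3, 3, 3], 0)
})

test_that("masking removes outside-mask maxima from the analysis", {
  d <- c(6, 6, 6)
  q <- array(1, d); q[6, 6, 6] <- 50 # global max outside the mask
  m <- array(TRUE, d); m[6, 6, 6] <- FALSE
  qm <- applyMasks(list(q), list(m))[[1]]
  expect_equal(qm[6, 6, 6], 0)
  ft <- frameThresholds(list(qm), list(m))
  expect_false(all(ft$maxLocations[1, ] == c(6, 6, 6)))
  expect_lte(ft$maxCurve[1], 1)
  # full mask: identity; empty mask: all-zero Q
  expect_identical(applyMasks(list(q), list(array(TRUE, d)))[[1]], q)
  expect_equal(max(abs(applyMasks(list(q), list(array(FALSE, d)))[[1]])), 0)
})

test_that("frame thresholds implement the cross-frame location average", {
  d <- c(4, 4, 4)
  m <- list(array(TRUE, d), array(TRUE, d))
  # two frames with maxima at different locations
  q1 <- array(0, d); q2 <- array(0, d)
  p1 <- c(2, 2, 2); p2 <- c(3, 3, 3)
  q1[2, 2, 2] <- 10; q1[3, 3, 3] <- 4
  q2[2, 2, 2] <- 3;  q2[3, 3, 3] <- 8
  ft <- frameThresholds(list(q1, q2), m)
  expect_equal(ft$thresholds, c((10 + 4) / 2, (3 + 8) / 2))
  expect_equal(ft$maxCurve, c(10, 8))
  expect_equal(ft$maxLocations, rbind(p1, p2), ignore_attr = TRUE)
  # single frame: threshold = frame maximum
  ft1 <- frameThresholds(list(q1), m[1])
  expect_equal(ft1$thresholds, 10)
  # identical frames: thr_i = max(Q_i)
  ftI <- frameThresholds(list(q1, q1), m)
  expect_equal(ftI$thresholds, c(10, 10))
  # thresholds never exceed the frame maximum
  expect_true(all(ft$thresholds <= ft$maxCurve))
})

test_that("the vortex-frame window bridges diastasis and finds both peaks", {
  # biphasic curve: E activity frames 3-8, A activity 14-19, zero elsewhere
  n <- 30
  curve <- numeric(n)
  curve[3:8] <- c(2, 5, 9, 8, 5, 2) * 100
  curve[14:19] <- c(1, 3, 5, 4.5, 3, 1) * 100
  thr <- rep(mean(curve) * 1.2, n)
  win <- vortexFrameWindow(curve, thr, kappaW = 0.5)
  expect_identical(win$vortexFrames, 3:19)
  expect_identical(win$peakFrames, c(5L, 16L))
  # constant positive curve: window = all frames
  winC <- vortexFrameWindow(rep(5, 10), rep(4, 10))
  expect_length(winC$vortexFrames, 10)
  # single-peak curve: both peak frames coincide
  c1 <- c(0, 0, 1, 3, 6, 3, 1, 0, 0, 0) * 100
  win1 <- vortexFrameWindow(c1, rep(mean(c1), 10))
  expect_identical(win1$peakFrames, c(5L, 5L))
  # all-zero curve: no activity
  expect_error(vortexFrameWindow(numeric(10), numeric(10)),
               "no vortex activity")
})

test_that("thresholded components are 26-connected, disjoint and size-filtered", {
  d <- c(12, 12, 12)
  q <- array(0, d)
  q[2:4, 2:4, 2:4] <- 5     # blob of 27
  q[8:10, 8:10, 8:10] <- 7  # blob of 27
  q[12, 12, 12] <- 9        # isolated voxel, dropped by minVoxels
  regs <- thresholdRegions(q, thr = 1, minVoxels = 5L)
  expect_length(regs, 2)
  expect_setequal(vapply(regs, nrow, integer(1)), c(27L, 27L))
  # partition: every above-threshold voxel in exactly one retained+dropped
  all <- do.call(rbind, thresholdRegions(q, 1, 1L))
  expect_equal(nrow(all), sum(q > 1))
  expect_equal(nrow(unique(all)), nrow(all))
  # diagonal touching merges under 26-connectivity
  q2 <- array(0, d)
  q2[2:3, 2:3, 2:3] <- 1; q2[4:5, 4:5, 4:5] <- 1
  expect_length(thresholdRegions(q2, 0.5, 1L), 1)
  expect_length(thresholdRegions(array(0, d), 1, 1L), 0)
})

test_that("first principal component finds the dominant Q pattern", {
  d <- c(8, 8, 8)
  blob <- array(0, d); blob[3:5, 3:5, 3:5] <- 1
  amp <- c(1, 3, 5, 2)
  frames <- lapply(amp, function(a) a * blob)
  thr <- rep(0.5, 4)
  pc <- firstPrincipalComponent(frames, thr, 1:4)
  # supported on the blob (zero rows stay zero up to SVD round-off)
  expect_lt(max(abs(pc@w1[blob == 0])), 1e-10)
  expect_true(blob[pc@w1MaxVoxel[1], pc@w1MaxVoxel[2], pc@w1MaxVoxel[3]] == 1)
  expect_gte(pc@w1[pc@w1MaxVoxel[1], pc@w1MaxVoxel[2], pc@w1MaxVoxel[3]], 0)
  expect_gt(pc@explainedVarianceRatio, 0.99)
  # two anti-correlated blobs: w1 dominated by the higher-variance one
  blob2 <- array(0, d); blob2[6:7, 6:7, 6:7] <- 1
  frames2 <- lapply(1:4, function(i)
    amp[i] * blob + (3 - 0.2 * amp[i]) * blob2)
  pc2 <- firstPrincipalComponent(frames2, rep(0.1, 4), 1:4)
  expect_gt(max(abs(pc2@w1[blob == 1])), 4 * max(abs(pc2@w1[blob2 == 1])))
  expect_error(firstPrincipalComponent(list(array(0, d), array(0, d)),
                                       c(0, 0), 1:2), "zero")
})

test_that("candidate factor follows the distance-normalized w1 sum", {
  g <- FlowGrid(c(8, 8, 8), spacing = c(1, 1, 1), nFrames = 1L)
  w1 <- array(0, c(8, 8, 8))
  vox <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))
  w1[vox] <- c(1, 2, 3)
  pc <- new("PCFields", w1 = w1, explainedVarianceRatio = 1,
            w1MaxLocation = c(3, 1, 1), w1MaxVoxel = c(4L, 2L, 2L))
  # long axis along x: dMax = max |x - 3| over voxels at x = 1, 2, 3
  cf <- candidateFactor(vox, pc, g, c(1, 0, 0), dFloor = 1)
  expect_equal(cf$dMax, 2)
  expect_equal(cf$fc, (1 + 2 + 3) / 2)
  # halving the distance doubles the factor (scale the axis distance)
  cf2 <- candidateFactor(vox, pc, g, c(0, 1, 0), dFloor = 1)
  expect_equal(cf2$dMax, 0) # all voxels share y -> floor applies
  expect_equal(cf2$fc, 6 / 1)
  # zero w1 over the region
  pc0 <- new("PCFields", w1 = array(0, c(8, 8, 8)),
             explainedVarianceRatio = 1, w1MaxLocation = c(3, 1, 1),
             w1MaxVoxel = c(4L, 2L, 2L))
  expect_equal(candidateFactor(vox, pc0, g, c(1, 0, 0))$fc, 0)
})

test_that("candidate selection keeps the top two compact regions", {
  mk <- function(fc, dMax) new("VortexCandidate",
                               voxels = matrix(1L, 1, 3), fc = fc,
                               dMax = dMax, centroid = c(0, 0, 0),
                               frame = 1L)
  sel <- selectCandidates(list(mk(5, 10), mk(3, 12), mk(1, 25)))
  expect_length(sel, 2)
  expect_equal(vapply(sel, function(x) x@fc, numeric(1)), c(5, 3))
  expect_length(selectCandidates(list(mk(0.1, 40))), 1)
  expect_length(selectCandidates(list()), 0)
})
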