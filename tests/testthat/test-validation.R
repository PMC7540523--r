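test_that("slice subsampling keeps every k-th slice and fills the gaps", {
  g <- FlowGrid(c(8, 8, 14), spacing = c(2, 2, 3.4), nFrames = 1L)
  m <- array(FALSE, g@shape)
  m[3:6, 3:6, 2:13] <- TRUE # 12 segmented slices
  ms <- MaskSeries(g, list(m), "reference")
  # k = 1 is the identity
  expect_identical(subsampleMaskSlices(ms, 1L)@frames, ms@frames)
  s2 <- subsampleMaskSlices(ms, 2L)
  expect_identical(provenance(s2), "subsampled-kd")
  # retained slices: 2, 4, ..., 12 -> 6 of the 12 segmented
  expect_equal(sum(vapply(2:13, function(k)
    any(s2@frames[[1]][, , k] != m[, , k]), logical(1))), 0)
  # nearest-fill makes each segmented slice a copy of a retained one
  s3 <- subsampleMaskSlices(ms, 3L)
  for (k in 2:13) {
    retained <- seq(2, 13, by = 3)
    src <- retained[which.min(abs(retained - k))]
    expect_identical(s3@frames[[1]][, , k], m[, , src])
  }
  # unsegmented slices stay empty
  expect_false(any(s3@frames[[1]][, , c(1, 14)]))
  expect_error(subsampleMaskSlices(ms, 13L), "fewer than 2")
})

test_that("static mask replicates one frame everywhere", {
  g <- FlowGrid(c(6, 6, 6), spacing = c(2, 2, 2), nFrames = 3L)
  ms <- MaskSeries(g, lapply(1:3, function(i) {
    m <- array(FALSE, g@shape); m[1:i, , ] <- TRUE; m
  }), "reference")
  st <- staticMask(ms, 2L)
  expect_identical(provenance(st), "static-end-dia")
  for (f in 1:3) expect_identical(st@frames[[f]], ms@frames[[2]])
  # already-static series: output equals input
  stat <- MaskSeries(g, rep(ms@frames[1], 3), "reference")
  expect_identical(staticMask(stat, 1L)@frames, stat@frames)
})

test_that("one-voxel morphology nests erode within dilate", {
  g <- FlowGrid(c(9, 9, 9), spacing = c(2, 2, 2), nFrames = 1L)
  m <- array(FALSE, g@shape); m[3:7, 3:7, 3:7] <- TRUE
  ms <- MaskSeries(g, list(m), "reference")
  er <- morphMask(ms, "erode")
  di <- morphMask(ms, "dilate")
  expect_identical(provenance(er), "eroded")
  expect_identical(provenance(di), "dilated")
  expect_true(all(m[er@frames[[1]]]))            # erode subset mask
  expect_true(all(di@frames[[1]][m]))            # mask subset dilate
  # 5^3 block erodes to its 3^3 interior under the 6-connected element
  expect_equal(sum(er@frames[[1]]), 27)
  expect_identical(unname(which(er@frames[[1]], arr.ind = TRUE)[1, ]),
                   c(4L, 4L, 4L))
  # a 1-voxel-thin sheet is emptied (with a warning)
  sheet <- array(FALSE, g@shape); sheet[, , 5] <- TRUE
  mss <- MaskSeries(g, list(sheet), "reference")
  expect_warning(er2 <- morphMask(mss, "erode"), "emptied")
  expect_false(any(er2@frames[[1]]))
})

test_that("Dice coefficient handles identity, disjoint and partial overlap", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); a[1:2, 1, 1] <- TRUE
  b <- array(FALSE, d); b[2:3, 1, 1] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, !a & FALSE), 0) # empty b
  expect_equal(diceCoefficient(array(FALSE, d), array(FALSE, d)), 1)
  expect_equal(diceCoefficient(a, b), 0.5) # |A|=|B|=2, 1 shared
  disj <- array(FALSE, d); disj[5:6, 6, 6] <- TRUE
  expect_equal(diceCoefficient(a, disj), 0)
  # symmetry and range on random sets
  set.seed(1)
  for (i in 1:5) {
    x <- array(runif(prod(d)) < 0.3, d)
    y <- array(runif(prod(d)) < 0.3, d)
    expect_equal(diceCoefficient(x, y), diceCoefficient(y, x))
    expect_gte(diceCoefficient(x, y), 0)
    expect_lte(diceCoefficient(x, y), 1)
  }
})

test_that("core Dice tolerates resampling but penalizes displacement", {
  g <- FlowGrid(c(24, 24, 24), spacing = c(2, 2, 2), nFrames = 1L)
  th1 <- seq(0, 2 * pi, length.out = 60)[-60]
  th2 <- seq(0, 2 * pi, length.out = 23)[-23]
  ctr <- c(23, 23, 23)
  mkc <- function(th, off = c(0, 0, 0)) sweep(
    cbind(14 * cos(th), 14 * sin(th), 0), 2, ctr + off, "+")
  expect_equal(coreDice(mkc(th1), mkc(th1), g), 1)
  # same circle at different sampling density
  expect_gte(coreDice(mkc(th1), mkc(th2), g), 0.9)
  # displaced by more than 2 voxels everywhere
  expect_lt(coreDice(mkc(th1), mkc(th1, off = c(9, 0, 0)), g), 0.5)
  expect_equal(coreDice(matrix(numeric(0), 0, 3), mkc(th1), g), 0)
})

test_that("Cohen's kappa matches the closed form and its edge cases", {
  # perfect agreement, balanced classes
  expect_equal(cohenKappa(rbind(c(10, 0), c(0, 10))), 1)
  # independence: agreement exactly at chance
  expect_equal(cohenKappa(rbind(c(9, 21), c(21, 49))), 0)
  # hand-evaluated mixed table
  m <- confusionMatrix2x2(a = 20, b = 5, c = 10, d = 15)
  po <- 35 / 50
  pe <- (25 * 30 + 25 * 20) / 2500
  expect_equal(cohenKappa(m), (po - pe) / (1 - pe))
  # kappa = 1 iff off-diagonal is empty (both classes present)
  expect_lt(cohenKappa(rbind(c(10, 1), c(0, 10))), 1)
  # degenerate margins: p_e = 1
  expect_equal(cohenKappa(rbind(c(50, 0), c(0, 0))), 1)
  expect_equal(cohenKappa(rbind(c(0, 50), c(0, 0))), 0)
  expect_gte(cohenKappa(rbind(c(1, 30), c(30, 1))), -1)
})

test_that("experiment harness computes mask conditions and self-comparison", {
  # tiny phantom so the full pipeline runs in seconds
  g <- FlowGrid(c(24, 24, 20), spacing = c(2.5, 2.5, 3), nFrames = 8L)
  ph <- biphasicPhantom(g, eaTiming = list(e = 2:3, a = 6:7),
                        noiseSd = 0.005, gradAmp = 0.01, seed = 2,
                        radius = 8, coreRadius = 3, circulation = 0.008,
                        maskSemiAxes = c(12, 12, 16))
  cf <- mvringConfig(hodgeTol = 1e-5)
  ref <- extractVortexRing(ph$velocity, ph$masks, cf)
  expect_true(any(ref@presence))
  ex <- runExperiment(ph$velocity, ph$masks, "reference", cf,
                      reference = ref)
  expect_equal(ex$kappa, 1)
  expect_equal(ex$regionDice, 1)
  expect_equal(ex$coreDice, 1)
  expect_equal(unname(ex$peakErrors$E), rep(0, 7), tolerance = 1e-12)
  # static masks on an already-static phantom are the identity condition
  exS <- runExperiment(ph$velocity, ph$masks, "end-dia", cf,
                       reference = ref)
  expect_equal(exS$kappa, 1)
  expect_equal(exS$regionDice, 1)
})
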