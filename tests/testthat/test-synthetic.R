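test_that("generators are seed-deterministic", {
  tt <- tractionDipoleTruth(c(16, 16), 4, softSubstrate())
  b1 <- simulateBeadImages(tt, 0.05, 1, 0.02, seed = 7)
  b2 <- simulateBeadImages(tt, 0.05, 1, 0.02, seed = 7)
  expect_identical(b1$reference, b2$reference)
  expect_identical(b1$deformed, b2$deformed)
  expect_false(identical(
    b1$reference, simulateBeadImages(tt, 0.05, 1, 0.02, seed = 8)$reference))

  n1 <- simulateNucleusSeries(0.4, 8, 0.1, 10, seed = 3)
  n2 <- simulateNucleusSeries(0.4, 8, 0.1, 10, seed = 3)
  expect_identical(n1$series@data, n2$series@data)

  s1 <- simulateSprouts(c(50, 90), seed = 4)
  s2 <- simulateSprouts(c(50, 90), seed = 4)
  expect_identical(s1$image, s2$image)

  f1 <- simulateFoci(c(3, 5), seed = 5)
  f2 <- simulateFoci(c(3, 5), seed = 5)
  expect_identical(f1$foci, f2$foci)

  c1 <- simulateCtTable(matrix(c(0, 1), 1, 2,
                               dimnames = list("Lmna", c("a", "b"))),
                        ctNoiseSd = 0.2, seed = 6)
  c2 <- simulateCtTable(matrix(c(0, 1), 1, 2,
                               dimnames = list("Lmna", c("a", "b"))),
                        ctNoiseSd = 0.2, seed = 6)
  expect_identical(c1, c2)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateNucleusSeries(0.3, 5, 0.1, 5, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("zero-force bead pair differs only by noise", {
  tt <- TractionTruth(matrix(0, 16, 16), matrix(0, 16, 16), 4,
                      softSubstrate())
  sim <- simulateBeadImages(tt, 0.05, 1, photonNoiseSd = 0, seed = 1)
  expect_identical(sim$reference, sim$deformed)
  expect_equal(max(abs(sim$field@ux)), 0)
  simN <- simulateBeadImages(tt, 0.05, 1, photonNoiseSd = 0.01, seed = 1)
  expect_lt(max(abs(simN$reference - simN$deformed)), 0.1)
})

test_that("bead pair generator enforces its preconditions", {
  tt <- tractionDipoleTruth(c(16, 16), 4, softSubstrate())
  expect_error(simulateBeadImages(tt, beadDensityPerUm2 = 1e-4, seed = 1),
               ">= 30 beads")
})

test_that("static nucleus series gives identical frames, white-noise limit
          decorrelates", {
  s0 <- simulateNucleusSeries(0, 8, 0, nFrames = 5, seed = 2)
  expect_equal(s0$series@data[, , 1], s0$series@data[, , 5])
  pcc0 <- curveData(computePCCCurve(
    nucleusPixelSeries(s0$series, s0$mask, register = FALSE), 4))$pcc
  expect_equal(pcc0, rep(1, 4))

  s1 <- simulateNucleusSeries(1, 1e-6, 0, nFrames = 8, seed = 2)
  pcc1 <- curveData(computePCCCurve(
    nucleusPixelSeries(s1$series, s1$mask, register = FALSE), 7))$pcc
  expect_lt(max(abs(pcc1)), 0.15)
})

test_that("mean PCC of generated nuclei follows the analytic curve", {
  alpha <- 0.5; tau <- 6; noise <- 0.1; nCells <- 120
  curves <- lapply(seq_len(nCells), function(i) {
    sim <- simulateNucleusSeries(alpha, tau, noise, 21, seed = 500 + i)
    computePCCCurve(nucleusPixelSeries(sim$series, sim$mask,
                                       register = FALSE), 15)
  })
  mc <- meanPCCCurve(curves)
  expected <- ((1 - alpha) + alpha * exp(-mc$table$lag_min / tau)) /
    (1 + noise^2)
  se <- (mc$table$ci_high - mc$table$ci_low) / (2 * stats::qt(0.975,
                                                              nCells - 1))
  inside <- abs(mc$table$mean_pcc - expected) <= 3 * se
  expect_gte(mean(inside), 0.9)
})

test_that("nucleus generator rejects invalid parameters", {
  expect_error(simulateNucleusSeries(0.4, 8, nFrames = 2, seed = 1),
               "nFrames")
  expect_error(simulateNucleusSeries(0.4, 8, nFrames = 5,
                                     maskDimPx = c(10, 10), seed = 1),
               ">= 200")
})

test_that("sprout generator produces the requested geometry", {
  s0 <- simulateSprouts(numeric(0), coreRadiusUm = 30, seed = 1)
  expect_equal(s0$meanLengthUm, 0)
  expect_gt(sum(s0$image), 0)  # the core is there

  s1 <- simulateSprouts(84, coreRadiusUm = 40, pixelSizeUm = 0.42, seed = 1)
  expect_equal(s1$truth$length_um, 84)
  # tip must sit (coreRadius + length) from the centre in the raster
  c0 <- (nrow(s1$image) - 1) / 2
  on <- which(s1$image > 0.5, arr.ind = TRUE)
  maxR <- max(sqrt((on[, 1] - 1 - c0)^2 + (on[, 2] - 1 - c0)^2))
  expect_equal(maxR * 0.42, 40 + 84, tolerance = 0.02)
})

test_that("foci generator respects counts and separations", {
  f0 <- simulateFoci(c(0, 0), seed = 1)
  expect_lt(max(f0$foci), 0.05)  # background noise only
  f <- simulateFoci(5, minSeparationUm = 1.5, seed = 2)
  expect_equal(f$truth$foci_count, 5L)
  expect_error(simulateFoci(80, minSeparationUm = 3, seed = 3),
               "nucleus 1")
})

test_that("gel generator matches analytic disk areas", {
  expect_error(simulateGelSeries(c(1, 1.2)), "non-increasing|exceed")
  expect_error(simulateGelSeries(c(0.9, 0.8)), "first")
  g <- simulateGelSeries(c(1, 0.5625), 100)
  a <- vapply(g$frames, sum, numeric(1))
  expect_equal(a[2] / a[1], 0.5625, tolerance = 0.005)
  g1 <- simulateGelSeries(1.0, 50)
  expect_length(g1$frames, 1)
})

test_that("ct table encodes fold changes exactly at zero noise", {
  lfc <- matrix(c(0, 0, 1, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("ctrl", "trt")))
  ct <- simulateCtTable(lfc, referenceGene = "Gapdh", nReplicates = 3,
                        ctNoiseSd = 0, seed = 1)
  dd <- deltaDeltaCt(ct, "Gapdh", "ctrl")
  expect_equal(dd$fold_change[dd$gene == "g1" & dd$condition == "trt"], 2)
  expect_equal(dd$fold_change[dd$gene == "g2" & dd$condition == "trt"], 1)
  expect_equal(dd$fold_change[dd$condition == "ctrl"], c(1, 1))
  expect_error(simulateCtTable(lfc, referenceCondition = "nope"),
               "referenceCondition")
})

test_that("noisy ct tables recover log2 folds without bias", {
  lfc <- matrix(c(0, 1.5), 1, 2,
                dimnames = list("g", c("ctrl", "trt")))
  l2 <- vapply(seq_len(300), function(i) {
    ct <- simulateCtTable(lfc, nReplicates = 3, ctNoiseSd = 0.2, seed = i)
    dd <- deltaDeltaCt(ct, "Gapdh", "ctrl")
    log2(dd$fold_change[dd$condition == "trt"])
  }, numeric(1))
  mcErr <- 3 * stats::sd(l2) / sqrt(length(l2))
  expect_lt(abs(mean(l2) - 1.5), mcErr + 0.01)
})
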