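test_that("nucleus pixel series extracts mask pixels in raster order", {
  fr1 <- matrix(1:16, 4, 4)
  fr2 <- fr1 * 2
  s <- ImageFrameSeries(list(fr1, fr2), frameIntervalMin = 1)
  mask <- matrix(FALSE, 4, 4)
  mask[c(2, 7, 10, 15)] <- TRUE
  px <- nucleusPixelSeries(s, mask, register = FALSE)
  expect_equal(px[, 1], fr1[mask])
  expect_equal(px[, 2], 2 * fr1[mask])

  mask1 <- matrix(FALSE, 4, 4); mask1[6] <- TRUE
  px1 <- nucleusPixelSeries(s, mask1, register = FALSE)
  expect_equal(dim(px1), c(1L, 2L))
  expect_error(nucleusPixelSeries(s, matrix(FALSE, 4, 4)), "empty")
})

test_that("registration removes whole-nucleus translation", {
  sim <- simulateNucleusSeries(0, 8, 0, nFrames = 3, seed = 9)
  # embed the nucleus with a margin so a shift does not push data off-frame
  embed <- function(m, dy = 0, dx = 0) {
    out <- matrix(0, 40, 40)
    out[(9 + dy):(32 + dy), (9 + dx):(32 + dx)] <- m
    out
  }
  fr <- embed(getFrame(sim$series, 1))
  shifted <- embed(getFrame(sim$series, 1), 2, -1)
  mask <- matrix(FALSE, 40, 40)
  mask[9:32, 9:32] <- sim$mask
  sim$mask <- mask
  s <- ImageFrameSeries(list(fr, shifted), frameIntervalMin = 1)
  # without registration the static texture decorrelates; with it, PCC = 1
  raw <- computePCCCurve(nucleusPixelSeries(s, sim$mask, register = FALSE),
                         1)
  reg <- computePCCCurve(nucleusPixelSeries(s, sim$mask, register = TRUE),
                         1)
  expect_lt(curveData(raw)$pcc, 0.9)
  expect_equal(curveData(reg)$pcc, 1, tolerance = 1e-9)
})

test_that("PCC curve matches hand-computed Pearson means and is affine
          invariant", {
  f1 <- c(3, 1, 4, 1); f2 <- c(5, 9, 2, 6); f3 <- c(5, 3, 5, 8)
  px <- cbind(f1, f2, f3)
  cv <- computePCCCurve(px, 2, frameIntervalMin = 2)
  expect_equal(curveData(cv)$lag_min, c(2, 4))
  expect_equal(curveData(cv)$n_pairs, c(2L, 1L))
  expect_equal(curveData(cv)$pcc[1],
               mean(c(pearsonByHand(f1, f2), pearsonByHand(f2, f3))))
  expect_equal(curveData(cv)$pcc[2], pearsonByHand(f1, f3))

  # identical frames -> 1 at every lag; affine transforms leave PCC at 1
  pxSame <- cbind(f1, f1, f1)
  expect_equal(curveData(computePCCCurve(pxSame, 2))$pcc, c(1, 1))
  pxAffPos <- cbind(f1, 2 * f1 + 7, 5 * f1 - 2)
  expect_equal(curveData(computePCCCurve(pxAffPos, 2))$pcc, c(1, 1))
})

test_that("PCC curve handles zero-variance frames", {
  px <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 4, 6, 8), c(1, 3, 2, 4))
  expect_warning(cv <- computePCCCurve(px, 2), "zero-variance")
  d <- curveData(cv)
  # frame 2 is constant: lag 1 keeps only (3,4); lag 2 keeps only (1,3)
  expect_equal(d$n_pairs, c(1L, 1L))
  expect_true(all(d$pcc >= -1 & d$pcc <= 1))
})

test_that("mean curve and CI behave on constructed inputs", {
  c1 <- PCCCurve(1:5, seq(1, 0.2, length.out = 5))
  mc <- meanPCCCurve(list(c1, c1, c1))
  expect_equal(mc$table$mean_pcc, c1@pcc)
  expect_equal(mc$table$ci_low, mc$table$ci_high)  # zero width

  c2 <- PCCCurve(1:5, -seq(1, 0.2, length.out = 5))
  mc2 <- meanPCCCurve(list(c1, c2))
  expect_equal(mc2$table$mean_pcc, rep(0, 5))

  c3 <- PCCCurve(1:4, rep(0.5, 4))
  expect_warning(mc3 <- meanPCCCurve(list(c1, c3)), "mismatched")
  expect_equal(mc3$table$lag_min, 1:4)
})

test_that("decay fit recovers an exact member of the model family", {
  cv <- PCCCurve(1:30, exp(-(1:30) / 5))
  f <- fitDecorrelation(cv)
  expect_equal(f@alpha, 1, tolerance = 1e-4)
  expect_equal(f@tauMin, 5, tolerance = 1e-4)
  expect_equal(f@eta, 0, tolerance = 1e-4)
  expect_true(f@converged)
})

test_that("flat curves yield near-zero drop rate with tau flagged", {
  f <- fitDecorrelation(PCCCurve(1:10, rep(1, 10)))
  expect_lt(f@alpha, 0.05)
  expect_equal(f@eta, 0, tolerance = 1e-6)
  expect_false(f@converged)  # tau unidentifiable

  set.seed(5)
  fn <- fitDecorrelation(PCCCurve(1:20, 0.95 + stats::rnorm(20, 0, 0.003)))
  expect_lt(fn@alpha, 0.05)
})

test_that("fit errors on bad curves and never beats its data", {
  expect_error(fitDecorrelation(PCCCurve(1:3, c(1, 0.9, 0.8))), "4 lags")
  cv <- PCCCurve(1:10, c(1, 0.9, NA, 0.7, 0.6, 0.5, 0.5, 0.5, 0.5, 0.5))
  expect_error(fitDecorrelation(cv), "non-finite")

  set.seed(6)
  y <- 0.6 + 0.4 * exp(-(1:25) / 7) + stats::rnorm(25, 0, 0.01)
  cv2 <- PCCCurve(1:25, pmin(1, y))
  f <- fitDecorrelation(cv2)
  # multi-start result is at least as good as the moment initialization
  p0 <- c(1 - min(cv2@pcc), 25 / 3, max(0, 1 - cv2@pcc[1]))
  rss0 <- sum((cv2@pcc - mechq:::decayModel(p0, 1:25))^2)
  expect_lte(f@rss, rss0 + 1e-12)
})

test_that("condition-mean fit recovers generating parameters", {
  alpha <- 0.4; tau <- 8
  curves <- lapply(seq_len(150), function(i) {
    sim <- simulateNucleusSeries(alpha, tau, 0.1, 33, seed = 2000 + i)
    computePCCCurve(nucleusPixelSeries(sim$series, sim$mask,
                                       register = FALSE), 31)
  })
  f <- fitDecorrelation(meanPCCCurve(curves)$curve)
  expect_lt(abs(f@alpha - alpha), 0.05)
  expect_lt(abs(f@tauMin - tau) / tau, 0.2)
})

test_that("larger drop rate in truth yields larger fitted drop rate", {
  # open-chromatin-like (large alpha) vs compact-like (small alpha)
  fitAlpha <- function(alpha, seedBase, n = 40) {
    curves <- lapply(seq_len(n), function(i) {
      sim <- simulateNucleusSeries(alpha, 8, 0.1, 25, seed = seedBase + i)
      computePCCCurve(nucleusPixelSeries(sim$series, sim$mask,
                                         register = FALSE), 20)
    })
    fitDecorrelation(meanPCCCurve(curves)$curve)@alpha
  }
  wins <- vapply(1:10, function(r) {
    fitAlpha(0.7, 3000 + 100 * r) > fitAlpha(0.3, 9000 + 100 * r)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
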