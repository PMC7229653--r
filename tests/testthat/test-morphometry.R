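test_that("nucleus segmentation finds disjoint and touching ellipses", {
  expect_equal(max(segmentNuclei(matrix(0, 60, 60))), 0)

  img <- matrix(0, 80, 80)
  m1 <- mechq:::ellipseMask(c(80, 80), 20, 25, 12, 8)
  m2 <- mechq:::ellipseMask(c(80, 80), 58, 52, 10, 9)
  img[m1] <- 0.9; img[m2] <- 0.9
  lab <- segmentNuclei(img, minAreaPx = 30)
  expect_equal(max(lab), 2)
  areas <- sort(tabulate(lab[lab > 0]))
  expect_equal(areas, sort(c(sum(m1), sum(m2))), tolerance = 0.02)

  # overlapping ellipses with distinct cores are split by the watershed
  img2 <- matrix(0, 80, 80)
  a <- mechq:::ellipseMask(c(80, 80), 30, 40, 12, 10)
  b <- mechq:::ellipseMask(c(80, 80), 50, 40, 12, 10)
  img2[a | b] <- 0.9
  lab2 <- segmentNuclei(img2, minAreaPx = 30)
  expect_equal(max(lab2), 2)
})

test_that("focus counting is exact on well-separated synthetic foci", {
  sim <- simulateFoci(c(0, 5, 3), minSeparationUm = 1.5, seed = 11)
  lab <- segmentNuclei(sim$nucleus)
  counts <- countFoci(sim$foci, lab, spotSigmaUm = 0.25,
                      pixelSizeUm = sim$pixelSizeUm)
  # map segmented labels back to generator nuclei via the known centres
  ids <- vapply(seq_len(nrow(sim$centers)), function(i)
    lab[round(sim$centers[i, 2]) + 1, round(sim$centers[i, 1]) + 1],
    integer(1))
  got <- counts$foci_count[match(ids, counts$nucleus_id)]
  expect_equal(got, c(0L, 5L, 3L))
  expect_error(countFoci(sim$foci, lab, spotSigmaUm = 0), "positive")
})

test_that("two foci below the filter resolution merge into one", {
  px <- 0.21; sigma <- 0.25
  sep <- 1.2 * sigma / px  # 1.2 sigma apart, in pixels
  img <- mechq:::renderSpots(rbind(c(30, 30), c(30 + sep, 30)),
                             c(60, 60), sigma / px)
  lab <- matrix(0L, 60, 60)
  lab[mechq:::diskMask(c(60, 60), 30, 30, 20)] <- 1L
  got <- countFoci(img, lab, spotSigmaUm = sigma, pixelSizeUm = px)
  expect_equal(got$foci_count, 1L)
})

test_that("focus counts ignore constant intensity offsets", {
  sim <- simulateFoci(c(4, 7), minSeparationUm = 1.5, seed = 12)
  lab <- segmentNuclei(sim$nucleus)
  c0 <- countFoci(sim$foci, lab, pixelSizeUm = sim$pixelSizeUm)
  c1 <- countFoci(sim$foci + 5, lab, pixelSizeUm = sim$pixelSizeUm)
  expect_equal(c0, c1)
})

test_that("region intensities follow the definitional arithmetic", {
  lab <- matrix(0L, 10, 20)
  lab[2:9, 2:9] <- 1L
  ch <- matrix(7, 10, 20)
  r <- regionIntensities(ch, lab, pixelSizeUm = 0.5)
  expect_equal(r$mean_intensity, 7)
  expect_equal(r$total_intensity, 7 * 64)
  expect_equal(r$area_um2, 64 * 0.25)

  ch[lab == 1] <- 2
  r2 <- regionIntensities(ch, lab)
  expect_equal(r2$total_intensity, 128)

  # 10 x 10 x 5 voxels of value 1, 0.5 um pixels, 1 um z step -> 4 per um^3
  lab3 <- matrix(0L, 12, 12); lab3[2:11, 2:11] <- 1L
  stack <- array(1, c(12, 12, 5))
  r3 <- regionIntensities(stack, lab3, pixelSizeUm = 0.5, zStepUm = 1)
  expect_equal(r3$total_per_volume_um3, 500 / (500 * 0.25 * 1))
  expect_warning(regionIntensities(ch, matrix(0L, 10, 20)), "no labelled")
})

test_that("intensity shift moves means by the constant", {
  sim <- simulateFoci(c(2, 3), seed = 13)
  lab <- segmentNuclei(sim$nucleus)
  r0 <- regionIntensities(sim$foci, lab)
  r1 <- regionIntensities(sim$foci + 3, lab)
  expect_equal(r1$mean_intensity, r0$mean_intensity + 3, tolerance = 1e-12)
})

test_that("normalization to the control mean", {
  ctrl <- c(8, 10, 12)
  expect_equal(mean(normalizedNuclearIntensity(ctrl, ctrl)), 1)
  expect_equal(normalizedNuclearIntensity(20, ctrl), 2)
  expect_error(normalizedNuclearIntensity(5, numeric(0)), "no nuclei")
  expect_error(normalizedNuclearIntensity(5, c(0, 0)), "zero")
  set.seed(14)
  ctrlN <- stats::rnorm(200, 10, 1)
  testN <- stats::rnorm(200, 15, 1)
  ratio <- mean(normalizedNuclearIntensity(testN, ctrlN))
  expect_equal(ratio, 1.5, tolerance = 3 * 0.1 / sqrt(200) / 10 + 0.02)
})

test_that("EdU-positive fraction with fixed and Otsu thresholds", {
  lab <- matrix(0L, 30, 120)
  for (i in 1:12) lab[10:20, (i * 10 - 8):(i * 10 - 2)] <- i
  edu <- matrix(0.1, 30, 120)
  edu[lab %in% 1:3] <- 0.9
  fixed <- eduPositiveFraction(edu, lab, threshold = 0.5)
  expect_equal(fixed$percent_positive, 25)
  all12 <- eduPositiveFraction(edu + 10, lab, threshold = 0.5)
  expect_equal(all12$percent_positive, 100)

  # bimodal means, 40% positive, Otsu rule
  set.seed(15)
  lab2 <- matrix(0L, 20, 500)
  for (i in 1:20) lab2[5:15, (i * 25 - 20):(i * 25 - 10)] <- i
  edu2 <- matrix(0, 20, 500)
  pos <- 1:8
  for (i in 1:20)
    edu2[lab2 == i] <- stats::rnorm(sum(lab2 == i),
                                    if (i %in% pos) 0.8 else 0.2, 0.05)
  ot <- eduPositiveFraction(edu2, lab2)
  expect_equal(ot$n_positive, 8)
  expect_equal(ot$percent_positive, 40)

  lab1 <- matrix(0L, 10, 10); lab1[3:7, 3:7] <- 1L
  expect_error(eduPositiveFraction(edu[1:10, 1:10], lab1), "fixed")
})

test_that("sprout metrics match constructed lengths", {
  s0 <- simulateSprouts(numeric(0), coreRadiusUm = 30, seed = 1)
  m0 <- sproutMetrics(s0$image, 0.42, coreRemovalRadiusUm = 8)
  expect_equal(m0$n_sprouts, 0L)
  expect_equal(m0$avg_sprout_length_um, 0)
  expect_equal(sproutMetrics(matrix(0, 50, 50), 0.42)$n_sprouts, 0L)

  s1 <- simulateSprouts(84, coreRadiusUm = 40, pixelSizeUm = 0.42,
                        seed = 1)
  m1 <- sproutMetrics(s1$image, 0.42, coreRemovalRadiusUm = 8)
  expect_equal(m1$n_sprouts, 1L)
  expect_equal(m1$avg_sprout_length_um, 84, tolerance = 0.03)

  set.seed(16)
  lens <- stats::runif(8, 40, 120)
  s8 <- simulateSprouts(lens, seed = 3)
  m8 <- sproutMetrics(s8$image, s8$pixelSizeUm, coreRemovalRadiusUm = 8)
  expect_equal(m8$n_sprouts, 8L)
  expect_equal(m8$avg_sprout_length_um, mean(lens), tolerance = 0.03)
  expect_gte(m8$total_skeleton_length_um,
             sum(m8$per_sprout_lengths_um) - 1e-9)
  expect_equal(m8$avg_sprout_length_um, mean(m8$per_sprout_lengths_um))
})

test_that("gel contraction recovers constructed area fractions", {
  g <- simulateGelSeries(c(1, 0.8, 0.56), 100)
  res <- gelContraction(g$frames)
  expect_equal(res$normalized_area, c(1, 0.8, 0.56), tolerance = 0.0125)
  expect_true(all(abs(res$normalized_area - c(1, 0.8, 0.56)) <= 0.01))
  expect_equal(res$percent_contraction[1], 0)
  expect_true(all(diff(res$normalized_area) <= 0))

  # analytic disk: radius 100 -> 75 px shrinks the area to 0.5625
  g2 <- simulateGelSeries(c(1, 0.5625), 100)
  res2 <- gelContraction(g2$frames)
  expect_equal(res2$normalized_area[2], 0.5625, tolerance = 0.005 / 0.5625)
  expect_equal(res2$percent_contraction[2], 43.75, tolerance = 0.02)

  same <- gelContraction(list(g$frames[[1]], g$frames[[1]]))
  expect_equal(same$normalized_area, c(1, 1))
  expect_equal(same$percent_contraction, c(0, 0))
  expect_error(gelContraction(list(g$frames[[1]])), "2 frames")
})

test_that("cell shape: circle, rectangle moments, and area arithmetic", {
  circ <- mechq:::diskMask(c(60, 60), 30, 30, 20)
  cs <- cellShape(circ, 0.21)
  expect_equal(cs$aspect_ratio, 1, tolerance = 0.05)

  rect <- matrix(FALSE, 50, 50)
  rect[21:30, 6:45] <- TRUE  # 10 x 40 pixels
  csr <- cellShape(rect)
  # discrete second moments of an m x n pixel rectangle: (m^2 - 1) / 12
  expected <- sqrt((40^2 - 1) / (10^2 - 1))
  expect_equal(csr$aspect_ratio, expected, tolerance = 1e-9)
  expect_lt(abs(csr$aspect_ratio - 4) / 4, 0.1)

  m <- matrix(FALSE, 20, 20); m[1:10, 1:5] <- TRUE
  expect_equal(cellShape(m, 0.21)$area_um2, 50 * 0.0441)
  tiny <- matrix(FALSE, 10, 10); tiny[1:2, 1] <- TRUE
  expect_error(cellShape(tiny), "5 pixels")
})

test_that("lengths scale with pixel size and areas with its square", {
  s <- simulateSprouts(c(60, 90), coreRadiusUm = 30, pixelSizeUm = 0.42,
                       seed = 5)
  m1 <- sproutMetrics(s$image, 0.42, coreRemovalRadiusUm = 6)
  m2 <- sproutMetrics(s$image, 0.84, coreRemovalRadiusUm = 12)
  expect_equal(m2$avg_sprout_length_um, 2 * m1$avg_sprout_length_um,
               tolerance = 1e-9)
  circ <- mechq:::diskMask(c(60, 60), 30, 30, 20)
  expect_equal(cellShape(circ, 0.42)$area_um2,
               4 * cellShape(circ, 0.21)$area_um2)
})
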