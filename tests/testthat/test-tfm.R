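test_that("bead detection localizes sub-pixel centres", {
  expect_equal(nrow(beadCoords(detectBeads(matrix(0, 20, 20), 3))), 0)
  img <- mechq:::renderSpots(cbind(10.3, 20.7), c(40, 40), sigmaPx = 1.5)
  b <- detectBeads(img, expectedDiameterPx = 3.5)
  expect_equal(nrow(beadCoords(b)), 1)
  expect_lt(sqrt(sum((beadCoords(b) - c(10.3, 20.7))^2)), 0.15)
  expect_error(detectBeads(img, expectedDiameterPx = 0), "positive")
})

test_that("duplicate detections within one radius are suppressed", {
  # two spots 0.4 radii apart -> a single (brighter-weighted) detection
  img <- mechq:::renderSpots(rbind(c(15, 15), c(15.7, 15)), c(30, 30), 1.5)
  expect_equal(nrow(beadCoords(detectBeads(img, 3.5))), 1)
})

test_that("bead linking recovers a uniform shift and drops far beads", {
  set.seed(1)
  pos <- cbind(stats::runif(40, 0, 100), stats::runif(40, 0, 100))
  ref <- BeadSet(pos)
  expect_equal(nrow(linkBeads(ref, ref, 3)),
               40)  # identity: all matched
  idLinks <- linkBeads(ref, ref, 3)
  expect_equal(max(abs(c(idLinks$ux_um, idLinks$uy_um))), 0)

  shifted <- BeadSet(sweep(pos, 2, c(1, -0.5), "+"))
  l <- linkBeads(ref, shifted, 3)
  expect_equal(nrow(l), 40)
  expect_equal(unique(round(l$ux_um, 9)), 1)
  expect_equal(unique(round(l$uy_um, 9)), -0.5)

  lone <- linkBeads(BeadSet(cbind(0, 0)), BeadSet(cbind(50, 50)), 3)
  expect_equal(nrow(lone), 0)
  expect_equal(nrow(linkBeads(BeadSet(matrix(numeric(0), 0, 2),
                                      numeric(0)), ref, 3)), 0)
})

test_that("assignment cost matches the brute-force permutation minimum", {
  for (s in 1:4) {
    set.seed(s)
    n <- 6
    c1 <- matrix(stats::runif(2 * n, 0, 10), n)
    c2 <- c1 + matrix(stats::rnorm(2 * n, 0, 0.6), n)
    maxd <- 2
    l <- linkBeads(BeadSet(c1), BeadSet(c2), maxd)
    cost <- sum(l$ux_um^2 + l$uy_um^2) +
      (n - nrow(l)) * 2 * maxd^2
    expect_equal(cost, bruteForceLinkCost(c1, c2, maxd), tolerance = 1e-12)
  }
})

test_that("normalized median test removes the planted outlier only", {
  d <- expand.grid(x_um = 1:5, y_um = 1:5)
  d$ux_um <- 1; d$uy_um <- 0
  d$ux_um[13] <- 10
  f <- filterOutliers(d, neighborhoodK = 8, threshold = 2)
  expect_equal(nrow(f), 24)
  expect_false(any(f$ux_um == 10))

  d$ux_um <- 1
  expect_equal(nrow(filterOutliers(d, 8, 2)), 25)
  d$ux_um <- 0  # all-zero field: the floor prevents 0/0
  expect_equal(nrow(filterOutliers(d, 8, 2)), 25)
  expect_warning(filterOutliers(d[1:4, ], 8, 2), "too few")
})

test_that("field interpolation reproduces constants and linear fields", {
  set.seed(3)
  pts <- data.frame(x_um = stats::runif(120, 0, 50),
                    y_um = stats::runif(120, 0, 50))
  pts$ux_um <- 2.5; pts$uy_um <- -1
  fld <- interpolateField(pts, 5, extentUm = c(50, 50))
  expect_equal(max(abs(fld@ux[fld@validMask] - 2.5)), 0, tolerance = 1e-9)

  pts$ux_um <- 0.1 * pts$x_um
  fld2 <- interpolateField(pts, 5, extentUm = c(50, 50))
  xs <- (col(fld2@ux) - 1) * 5
  expect_lt(max(abs(fld2@ux - 0.1 * xs)[fld2@validMask]), 1e-6)

  col3 <- data.frame(x_um = 1:5, y_um = 2 * (1:5), ux_um = 1, uy_um = 1)
  expect_error(interpolateField(col3, 1), "collinear")
})

test_that("smooth random field is gridded within 5% RMS", {
  set.seed(4)
  pts <- data.frame(x_um = stats::runif(400, 0, 60),
                    y_um = stats::runif(400, 0, 60))
  fx <- function(x, y) sin(x / 12) + 0.5 * cos(y / 9)
  fy <- function(x, y) cos(x / 15) * sin(y / 10)
  pts$ux_um <- fx(pts$x_um, pts$y_um)
  pts$uy_um <- fy(pts$x_um, pts$y_um)
  fld <- interpolateField(pts, 4, extentUm = c(60, 60))
  xs <- (col(fld@ux) - 1) * 4; ys <- (row(fld@ux) - 1) * 4
  v <- fld@validMask
  rmsErr <- sqrt(mean((fld@ux[v] - fx(xs[v], ys[v]))^2 +
                      (fld@uy[v] - fy(xs[v], ys[v]))^2))
  rmsField <- sqrt(mean(fx(xs[v], ys[v])^2 + fy(xs[v], ys[v])^2))
  expect_lt(rmsErr / rmsField, 0.05)
})

test_that("FTTC inversion is zero on zero input and linear in the input", {
  z <- DisplacementField(matrix(0, 16, 16), matrix(0, 16, 16), 4)
  tz <- invertFTTC(z, softSubstrate(), 1e-9)
  expect_equal(max(tz@magnitude), 0)
  expect_equal(strainEnergy(tz), 0)

  tt <- tractionDipoleTruth(c(32, 32), 4, softSubstrate())
  fld <- forwardDisplacement(tt)
  tr1 <- invertFTTC(fld, softSubstrate(), 1e-9)
  fld3 <- DisplacementField(3 * fld@ux, 3 * fld@uy, 4)
  tr3 <- invertFTTC(fld3, softSubstrate(), 1e-9)
  expect_equal(tr3@tx, 3 * tr1@tx, tolerance = 1e-10)

  expect_error(invertFTTC(fld, softSubstrate(), -1), "nonnegative")
  small <- DisplacementField(matrix(0, 4, 4), matrix(0, 4, 4), 4)
  expect_error(invertFTTC(small, softSubstrate()), "8 x 8")
})

test_that("noiseless round trip recovers tractions and strain energy", {
  tt <- tractionDipoleTruth(c(64, 64), 4, softSubstrate(),
                            magnitudePa = 100, separationUm = 40,
                            patchSigmaUm = 8)
  fld <- forwardDisplacement(tt)
  tr <- invertFTTC(fld, softSubstrate(), lambda = 1e-9)
  expect_lt(relL2(tr@tx, tr@ty, tt@tx, tt@ty), 0.05)
  uTruth <- mechq:::strainEnergyQuadrature(tt@tx, tt@ty, fld@ux, fld@uy, 4)
  expect_lt(abs(strainEnergy(tr) - uTruth) / uTruth, 0.05)
  expect_gte(strainEnergy(tr), 0)
})

test_that("round-trip error grows with displacement noise at fixed lambda", {
  tt <- tractionDipoleTruth(c(32, 32), 4, softSubstrate())
  fld <- forwardDisplacement(tt)
  lam <- 1e-4
  errAt <- function(noise, seed = 11) {
    set.seed(seed)
    f <- DisplacementField(fld@ux + stats::rnorm(length(fld@ux), 0, noise),
                           fld@uy + stats::rnorm(length(fld@uy), 0, noise),
                           4)
    tr <- invertFTTC(f, softSubstrate(), lam)
    relL2(tr@tx, tr@ty, tt@tx, tt@ty)
  }
  errs <- vapply(c(0, 0.02, 0.1), errAt, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("total traction magnitude is non-increasing in lambda", {
  tt <- tractionDipoleTruth(c(32, 32), 4, softSubstrate())
  fld <- forwardDisplacement(tt)
  mags <- vapply(c(1e-6, 1e-4, 1e-3, 1e-2), function(l)
    sum(invertFTTC(fld, softSubstrate(), l)@magnitude), numeric(1))
  expect_true(all(diff(mags) <= 1e-9 * mags[1]))
})

test_that("energy quadrature has the stated unit conversion", {
  # uniform 100 Pa aligned with uniform 1 um over 100 x 100 um^2
  n <- 11; h <- 10  # nodes spaced 10 um; cell area sums to 100x100 um^2
  tx <- matrix(100, n, n); ux <- matrix(1, n, n)
  zero <- matrix(0, n, n)
  u <- mechq:::strainEnergyQuadrature(tx, zero, ux, zero, h)
  expect_equal(u, 0.5 * 100 * 1 * (n * n * h^2) * 1e-6)
  expect_equal(mechq:::strainEnergyQuadrature(tx, zero, ux, zero,
                                              sqrt(10000 / n^2)),
               5e-1, tolerance = 1e-12)
})

test_that("strain-energy series finds the constructed peak", {
  sub <- softSubstrate()
  base <- tractionDipoleTruth(c(32, 32), 4, sub, magnitudePa = 100)
  ramp <- c(0, 0.5, 1, 0.6, 0.2)
  fields <- lapply(ramp, function(s) {
    f <- forwardDisplacement(base)
    DisplacementField(s * f@ux, s * f@uy, 4)
  })
  res <- strainEnergySeries(fields, sub, lambda = 1e-9,
                            frameIntervalMin = 30)
  expect_equal(nrow(res$series), 5)
  expect_equal(res$series$time_min, c(0, 30, 60, 90, 120))
  expect_equal(which.max(res$series$strain_energy_pJ), 3)
  # energies scale as s^2; peak within 5% of the constructed maximum
  eMax <- res$series$strain_energy_pJ[3]
  expect_equal(res$peak_pJ, eMax)
  expect_equal(res$series$strain_energy_pJ[2] / eMax, 0.25,
               tolerance = 0.05)
  # identical fields give identical energies
  same <- strainEnergySeries(fields[c(3, 3, 3)], sub, 1e-9)
  expect_lt(diff(range(same$series$strain_energy_pJ)) /
              same$peak_pJ, 1e-9)
  # zero single field
  z <- DisplacementField(matrix(0, 16, 16), matrix(0, 16, 16), 4)
  rz <- strainEnergySeries(list(z), sub, 1e-9)
  expect_equal(rz$peak_pJ, 0)
})
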