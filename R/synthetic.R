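## Synthetic-data generators. Every stage of the analysis has a generator that
## produces its input together with the ground truth it should recover, so the
## whole pipeline is testable without experimental images. All generators are
## seed-reproducible and leave the caller's RNG state untouched.

#' Balanced traction dipole on a regular grid
#'
#' Builds a ground-truth traction field made of two opposed Gaussian traction
#' patches (a force dipole), the simplest field a half-space inversion can
#' represent: the net force is zero by construction and the constructor
#' removes any residual numerical imbalance.
#'
#' @param gridShape integer pair (rows, cols).
#' @param spacingUm grid spacing (micrometres).
#' @param substrate an [ElasticSubstrate-class].
#' @param magnitudePa peak traction of each patch (Pa).
#' @param separationUm centre-to-centre distance of the two patches
#'   (micrometres); default one quarter of the field width.
#' @param patchSigmaUm Gaussian width of each patch (micrometres); default
#'   twice the grid spacing.
#' @param angleRad orientation of the dipole axis (radians, 0 = x axis).
#' @return A [TractionTruth-class].
#' @export
tractionDipoleTruth <- function(gridShape, spacingUm, substrate,
                                magnitudePa = 100,
                                separationUm = gridShape[2] * spacingUm / 4,
                                patchSigmaUm = 2 * spacingUm,
                                angleRad = 0) {
  nr <- gridShape[1]; nc <- gridShape[2]
  cx <- (nc - 1) * spacingUm / 2
  cy <- (nr - 1) * spacingUm / 2
  ax <- cos(angleRad); ay <- sin(angleRad)
  xs <- matrix(rep((seq_len(nc) - 1) * spacingUm, each = nr), nr)
  ys <- matrix(rep((seq_len(nr) - 1) * spacingUm, times = nc), nr)
  patch <- function(px, py) {
    exp(-((xs - px)^2 + (ys - py)^2) / (2 * patchSigmaUm^2))
  }
  g1 <- patch(cx - ax * separationUm / 2, cy - ay * separationUm / 2)
  g2 <- patch(cx + ax * separationUm / 2, cy + ay * separationUm / 2)
  # contractile pair: patches pull toward each other along the dipole axis
  tx <- magnitudePa * ax * (g1 - g2)
  ty <- magnitudePa * ay * (g1 - g2)
  TractionTruth(tx, ty, spacingUm, substrate)
}

#' Random balanced traction field
#'
#' Superposition of randomly placed, randomly oriented Gaussian force dipoles,
#' mean-subtracted so the net force vanishes exactly. Used for property tests
#' of the forward/inverse traction machinery.
#'
#' @inheritParams tractionDipoleTruth
#' @param nDipoles number of dipoles to superpose.
#' @param seed RNG seed.
#' @return A [TractionTruth-class].
#' @export
randomTractionTruth <- function(gridShape, spacingUm, substrate,
                                nDipoles = 3, magnitudePa = 100,
                                patchSigmaUm = 2 * spacingUm, seed = 1) {
  nr <- gridShape[1]; nc <- gridShape[2]
  withSeed(seed, {
    xs <- matrix(rep((seq_len(nc) - 1) * spacingUm, each = nr), nr)
    ys <- matrix(rep((seq_len(nr) - 1) * spacingUm, times = nc), nr)
    tx <- matrix(0, nr, nc); ty <- matrix(0, nr, nc)
    lim <- c(0.25, 0.75)  # keep patches away from the border
    for (i in seq_len(nDipoles)) {
      ang <- stats::runif(1, 0, 2 * pi)
      sep <- stats::runif(1, 3, 6) * spacingUm
      px <- stats::runif(1, lim[1], lim[2]) * (nc - 1) * spacingUm
      py <- stats::runif(1, lim[1], lim[2]) * (nr - 1) * spacingUm
      amp <- magnitudePa * stats::runif(1, 0.5, 1)
      g1 <- exp(-((xs - px + cos(ang) * sep / 2)^2 +
                  (ys - py + sin(ang) * sep / 2)^2) / (2 * patchSigmaUm^2))
      g2 <- exp(-((xs - px - cos(ang) * sep / 2)^2 +
                  (ys - py - sin(ang) * sep / 2)^2) / (2 * patchSigmaUm^2))
      tx <- tx + amp * cos(ang) * (g1 - g2)
      ty <- ty + amp * sin(ang) * (g1 - g2)
    }
    TractionTruth(tx, ty, spacingUm, substrate)
  })
}

#' Simulate a reference/deformed bead-image pair
#'
#' Renders a random field of Gaussian fiducial beads, computes the forward
#' Boussinesq displacement of a known traction field, and renders the same
#' beads translated by the displacement at each bead position. Additive
#' Gaussian noise approximates photon noise. The pair, the gridded truth
#' displacement field and the per-bead truth displacements are returned, so
#' bead detection, linking and the traction inversion can all be checked
#' against ground truth.
#'
#' @param truth a [TractionTruth-class]; its validity enforces a balanced
#'   field and a compressible substrate (`poissonRatio < 0.5`).
#' @param beadDensityPerUm2 bead number density (beads per square micrometre);
#'   must yield at least 30 beads in the field.
#' @param beadDiameterUm apparent bead diameter (FWHM of the rendered Gaussian
#'   spot, micrometres).
#' @param photonNoiseSd standard deviation of the additive Gaussian noise,
#'   relative to unit spot amplitude.
#' @param seed RNG seed; identical arguments and seed give identical output.
#' @param pixelSizeUm image pixel size (micrometres); default a quarter of the
#'   traction grid spacing.
#' @return A list with `reference` and `deformed` image matrices, `field`
#'   (the truth [DisplacementField-class]), `beads` (data.frame `x_um`,
#'   `y_um`, `ux_um`, `uy_um`), and `pixelSizeUm`.
#' @export
simulateBeadImages <- function(truth, beadDensityPerUm2 = 0.05,
                               beadDiameterUm = 1, photonNoiseSd = 0.02,
                               seed = 1,
                               pixelSizeUm = truth@spacingUm / 4) {
  stopifnot(is(truth, "TractionTruth"))
  validObject(truth)
  d <- dim(truth@tx)
  h <- truth@spacingUm
  Lx <- (d[2] - 1) * h; Ly <- (d[1] - 1) * h
  nBeads <- round(beadDensityPerUm2 * Lx * Ly)
  if (nBeads < 30)
    stop("bead density too low: needs >= 30 beads in the field, got ",
         nBeads)
  field <- forwardDisplacement(truth)
  withSeed(seed, {
    bx <- stats::runif(nBeads, 0, Lx)
    by <- stats::runif(nBeads, 0, Ly)
    ux <- bilinearAt(field@ux, h, bx, by)
    uy <- bilinearAt(field@uy, h, bx, by)
    dimPx <- c(round(Ly / pixelSizeUm) + 1, round(Lx / pixelSizeUm) + 1)
    sigmaPx <- beadDiameterUm / 2.355 / pixelSizeUm
    ref <- renderSpots(cbind(bx, by) / pixelSizeUm, dimPx, sigmaPx)
    def <- renderSpots(cbind(bx + ux, by + uy) / pixelSizeUm, dimPx, sigmaPx)
    if (photonNoiseSd > 0) {
      ref <- ref + matrix(stats::rnorm(prod(dimPx), 0, photonNoiseSd),
                          dimPx[1])
      def <- def + matrix(stats::rnorm(prod(dimPx), 0, photonNoiseSd),
                          dimPx[1])
    }
    list(reference = ref, deformed = def, field = field,
         beads = data.frame(x_um = bx, y_um = by, ux_um = ux, uy_um = uy),
         pixelSizeUm = pixelSizeUm)
  })
}

#' Simulate a nucleus time-lapse with known decorrelation dynamics
#'
#' Generates per-pixel intensities `I_t = B + S + D_t + e_t` inside an
#' elliptical nucleus mask: `S` is a static random texture with variance
#' `1 - alpha`, `D_t` a stationary AR(1) process with variance `alpha` and
#' lag-k autocorrelation `exp(-k dt / tau)` (its autocorrelation is exactly
#' exponential, so the decay model fitted downstream is the correct generative
#' family), and `e_t` independent noise with standard deviation `noiseSd`
#' (all relative to unit texture variance). The expected Pearson decorrelation
#' curve is therefore `((1 - alpha) + alpha exp(-t/tau)) / (1 + noiseSd^2)`:
#' the model curve scaled by a lag-independent factor that the fitted noise
#' term absorbs.
#'
#' @param alpha drop rate in `[0, 1]`: fraction of pixel variance that
#'   decorrelates.
#' @param tauMin time constant of the decorrelation (minutes).
#' @param noiseSd measurement noise SD as a fraction of the texture SD.
#' @param nFrames number of frames (>= 3).
#' @param frameIntervalMin frame interval (minutes).
#' @param maskDimPx frame size (pixels); the mask is the inscribed ellipse and
#'   must cover at least 200 pixels.
#' @param seed RNG seed.
#' @return A list with `series` (an [ImageFrameSeries-class]), `mask`
#'   (logical matrix) and `truth` (the generating parameters).
#' @export
simulateNucleusSeries <- function(alpha, tauMin, noiseSd = 0, nFrames = 33,
                                  frameIntervalMin = 1,
                                  maskDimPx = c(24, 24), seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, tauMin > 0, noiseSd >= 0,
            frameIntervalMin > 0)
  if (nFrames < 3) stop("nFrames must be >= 3")
  mask <- ellipseMask(maskDimPx, (maskDimPx[2] - 1) / 2,
                      (maskDimPx[1] - 1) / 2,
                      maskDimPx[2] / 2 - 0.5, maskDimPx[1] / 2 - 0.5)
  npx <- sum(mask)
  if (npx < 200)
    stop("mask covers ", npx, " pixels; needs >= 200")
  withSeed(seed, {
    baseline <- 10
    S <- stats::rnorm(npx, 0, sqrt(1 - alpha))
    phi <- exp(-frameIntervalMin / tauMin)
    D <- matrix(0, npx, nFrames)
    if (alpha > 0) {
      D[, 1] <- stats::rnorm(npx, 0, sqrt(alpha))
      innovSd <- sqrt(alpha * (1 - phi^2))
      for (t in seq_len(nFrames - 1)) {
        D[, t + 1] <- phi * D[, t] + stats::rnorm(npx, 0, innovSd)
      }
    }
    eps <- if (noiseSd > 0) {
      matrix(stats::rnorm(npx * nFrames, 0, noiseSd), npx)
    } else matrix(0, npx, nFrames)
    frames <- array(0, c(maskDimPx, nFrames))
    for (t in seq_len(nFrames)) {
      fr <- matrix(0, maskDimPx[1], maskDimPx[2])
      fr[mask] <- baseline + S + D[, t] + eps[, t]
      frames[, , t] <- fr
    }
    list(series = ImageFrameSeries(frames, pixelSizeUm = 0.21,
                                   frameIntervalMin = frameIntervalMin),
         mask = mask,
         truth = list(alpha = alpha, tauMin = tauMin, noiseSd = noiseSd,
                      nFrames = nFrames,
                      frameIntervalMin = frameIntervalMin))
  })
}

#' Simulate a spheroid with sprouts of known length
#'
#' Renders a bright disk (the spheroid core) with thin bright paths radiating
#' outward. Each sprout is drawn as a unit-speed polyline starting on the core
#' boundary, so its geodesic length equals the requested length exactly; a
#' small curvature can be applied (the polyline turns by `curvatureRad` over
#' its course) without changing the arc length. Sprouts are laid out at
#' jittered equispaced angles; if two rasterized sprouts collide the layout is
#' regenerated with fresh jitter, and generation fails after `maxRetries`.
#'
#' @param sproutLengthsUm positive sprout lengths (micrometres); may be empty
#'   for a core-only image.
#' @param coreRadiusUm spheroid core radius (micrometres).
#' @param pixelSizeUm pixel size (micrometres).
#' @param curvatureRad total heading change along each sprout (radians).
#' @param seed RNG seed.
#' @param maxRetries layout attempts before giving up.
#' @return A list with `image` (matrix), `truth` (data.frame `sprout_id`,
#'   `length_um`), `meanLengthUm`, `coreRadiusUm` and `pixelSizeUm`.
#' @export
simulateSprouts <- function(sproutLengthsUm, coreRadiusUm = 40,
                            pixelSizeUm = 0.42, curvatureRad = 0,
                            seed = 1, maxRetries = 20) {
  stopifnot(all(sproutLengthsUm > 0), coreRadiusUm > 0, pixelSizeUm > 0)
  n <- length(sproutLengthsUm)
  maxLen <- if (n) max(sproutLengthsUm) else 0
  extentPx <- 2 * ceiling((coreRadiusUm + maxLen + 6) / pixelSizeUm) + 1
  dimPx <- c(extentPx, extentPx)
  c0 <- (extentPx - 1) / 2  # centre, 0-based pixels
  corePx <- coreRadiusUm / pixelSizeUm
  stepUm <- pixelSizeUm / 2
  paint <- expand.grid(dr = -2:2, dc = -2:2)
  paint <- paint[paint$dr^2 + paint$dc^2 <= 1.3^2, ]
  withSeed(seed, {
    for (attempt in seq_len(maxRetries)) {
      img <- matrix(0, dimPx[1], dimPx[2])
      owner <- matrix(0L, dimPx[1], dimPx[2])
      img[diskMask(dimPx, c0, c0, corePx)] <- 1
      base <- if (n) seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] else
        numeric(0)
      angles <- base + stats::runif(n, -0.2, 0.2) * (2 * pi / max(n, 1)) +
        stats::runif(1, 0, 2 * pi)
      collided <- FALSE
      for (i in seq_len(n)) {
        nSteps <- ceiling(sproutLengthsUm[i] / stepUm)
        ds <- sproutLengthsUm[i] / nSteps
        heading <- angles[i] +
          curvatureRad * (seq_len(nSteps) - 0.5) / nSteps
        px <- (c0 * pixelSizeUm + coreRadiusUm * cos(angles[i]) +
                 cumsum(ds * cos(heading))) / pixelSizeUm
        py <- (c0 * pixelSizeUm + coreRadiusUm * sin(angles[i]) +
                 cumsum(ds * sin(heading))) / pixelSizeUm
        rows <- rep(round(py) + 1, each = nrow(paint)) + paint$dr
        cols <- rep(round(px) + 1, each = nrow(paint)) + paint$dc
        keep <- rows >= 1 & rows <= dimPx[1] & cols >= 1 & cols <= dimPx[2]
        idx <- cbind(rows[keep], cols[keep])
        hit <- owner[idx]
        if (any(hit != 0L & hit != i)) { collided <- TRUE; break }
        owner[idx] <- i
        img[idx] <- 1
      }
      if (!collided) {
        return(list(image = img,
                    truth = data.frame(sprout_id = seq_len(n),
                                       length_um = as.numeric(sproutLengthsUm)),
                    meanLengthUm = if (n) mean(sproutLengthsUm) else 0,
                    coreRadiusUm = coreRadiusUm,
                    pixelSizeUm = pixelSizeUm))
      }
    }
    stop("could not lay out ", n, " non-overlapping sprouts after ",
         maxRetries, " attempts")
  })
}

#' Simulate nuclei with a known number of bright foci
#'
#' Generates a two-channel field: elliptical nuclei (nucleus channel) each
#' containing the requested number of Gaussian foci (foci channel), with all
#' pairwise focus separations at least `minSeparationUm`. Placement is by
#' rejection sampling inside the inner 75% of each nucleus; an infeasible
#' packing raises an error naming the offending nucleus.
#'
#' @param fociCounts integer vector, one requested count per nucleus.
#' @param minSeparationUm minimal pairwise focus separation (micrometres).
#' @param pixelSizeUm pixel size (micrometres).
#' @param nucleusRadiusUm mean nucleus radius (micrometres).
#' @param fociSigmaUm Gaussian width of a focus (micrometres).
#' @param seed RNG seed.
#' @return A list with `nucleus` and `foci` channel matrices, `truth`
#'   (data.frame `nucleus_id`, `foci_count`), `centers` (nucleus centres, px)
#'   and `pixelSizeUm`.
#' @export
simulateFoci <- function(fociCounts, minSeparationUm = 1,
                         pixelSizeUm = 0.21, nucleusRadiusUm = 5,
                         fociSigmaUm = 0.25, seed = 1) {
  stopifnot(all(fociCounts >= 0), minSeparationUm > 0)
  n <- length(fociCounts)
  rPx <- nucleusRadiusUm / pixelSizeUm
  cellPx <- ceiling(2.8 * rPx)
  perRow <- ceiling(sqrt(n))
  nRows <- ceiling(n / perRow)
  dimPx <- c(nRows * cellPx, perRow * cellPx)
  withSeed(seed, {
    nucleus <- matrix(0, dimPx[1], dimPx[2])
    centers <- matrix(0, n, 2)
    fociPos <- vector("list", n)
    for (i in seq_len(n)) {
      row <- (i - 1) %/% perRow
      col <- (i - 1) %% perRow
      cx <- col * cellPx + cellPx / 2 + stats::runif(1, -2, 2)
      cy <- row * cellPx + cellPx / 2 + stats::runif(1, -2, 2)
      a <- rPx * stats::runif(1, 0.85, 1.15)
      b <- rPx * stats::runif(1, 0.7, 0.95)
      th <- stats::runif(1, 0, pi)
      nucleus[ellipseMask(dimPx, cx, cy, a, b, th)] <- 0.8
      centers[i, ] <- c(cx, cy)
      # rejection-sample focus positions inside the inner 75% of the ellipse
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0
      sepPx <- minSeparationUm / pixelSizeUm
      while (nrow(pts) < fociCounts[i]) {
        tries <- tries + 1
        if (tries > 5000)
          stop("cannot place ", fociCounts[i], " foci at separation ",
               minSeparationUm, " um in nucleus ", i)
        u <- stats::runif(1, 0, 1); phi <- stats::runif(1, 0, 2 * pi)
        ex <- 0.75 * sqrt(u) * cos(phi) * a
        ey <- 0.75 * sqrt(u) * sin(phi) * b
        px <- cx + ex * cos(th) - ey * sin(th)
        py <- cy + ex * sin(th) + ey * cos(th)
        if (nrow(pts) == 0 ||
            min(sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)) >= sepPx) {
          pts <- rbind(pts, c(px, py))
        }
      }
      fociPos[[i]] <- pts
    }
    allPts <- do.call(rbind, fociPos[lengths(fociPos) > 0])
    foci <- renderSpots(if (is.null(allPts)) matrix(0, 0, 2) else allPts,
                        dimPx, fociSigmaUm / pixelSizeUm)
    foci <- foci + matrix(stats::rnorm(prod(dimPx), 0, 0.005), dimPx[1])
    list(nucleus = nucleus, foci = foci,
         truth = data.frame(nucleus_id = seq_len(n),
                            foci_count = as.integer(fociCounts)),
         centers = centers, pixelSizeUm = pixelSizeUm)
  })
}

#' Simulate a shrinking-gel silhouette series
#'
#' Renders filled-disk silhouettes whose areas are the stated fractions of the
#' first frame's area, emulating a collagen-gel contraction assay imaged over
#' days.
#'
#' @param areaFractions normalized areas in `(0, 1]`, non-increasing, first
#'   exactly 1.
#' @param initialRadiusPx disk radius in frame 1 (pixels).
#' @return A list with `frames` (list of matrices) and `truth` (the
#'   fractions).
#' @export
simulateGelSeries <- function(areaFractions, initialRadiusPx = 100) {
  stopifnot(initialRadiusPx > 2)
  if (!length(areaFractions) || abs(areaFractions[1] - 1) > 1e-12)
    stop("first area fraction must be 1")
  if (any(areaFractions > 1 + 1e-12))
    stop("area fractions must not exceed 1")
  if (any(diff(areaFractions) > 1e-12))
    stop("area fractions must be non-increasing")
  if (any(areaFractions <= 0))
    stop("area fractions must be positive")
  extent <- 2 * ceiling(initialRadiusPx * 1.2) + 1
  c0 <- (extent - 1) / 2
  frames <- lapply(areaFractions, function(f) {
    img <- matrix(0, extent, extent)
    img[diskMask(c(extent, extent), c0, c0, initialRadiusPx * sqrt(f))] <- 1
    img
  })
  list(frames = frames, truth = as.numeric(areaFractions))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Generates threshold-cycle values consistent with the requested log2 fold
#' changes under perfect amplification efficiency (one Ct unit per two-fold),
#' relative to a housekeeping reference gene whose expression is constant
#' across conditions. Gaussian noise of SD `ctNoiseSd` is added to every Ct.
#'
#' @param log2FoldChanges numeric matrix of true log2 fold changes, rows =
#'   genes (rownames required), columns = conditions (colnames required); the
#'   column for `referenceCondition` must be zero.
#' @param referenceGene housekeeping gene name added to the table.
#' @param referenceCondition baseline condition; default the first column.
#' @param nReplicates replicates per (gene, condition).
#' @param ctNoiseSd Gaussian noise SD on each Ct value.
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `condition`, `replicate`, `ct`.
#' @export
simulateCtTable <- function(log2FoldChanges, referenceGene = "Gapdh",
                            referenceCondition = colnames(log2FoldChanges)[1],
                            nReplicates = 3, ctNoiseSd = 0, seed = 1) {
  stopifnot(is.matrix(log2FoldChanges),
            !is.null(rownames(log2FoldChanges)),
            !is.null(colnames(log2FoldChanges)))
  if (!referenceCondition %in% colnames(log2FoldChanges))
    stop("referenceCondition not among conditions")
  if (max(abs(log2FoldChanges[, referenceCondition])) > 1e-12)
    stop("log2 fold changes must be 0 in the reference condition")
  genes <- rownames(log2FoldChanges)
  conditions <- colnames(log2FoldChanges)
  baseCt <- stats::setNames(22 + seq_along(genes) / 2, genes)
  withSeed(seed, {
    rows <- expand.grid(replicate = seq_len(nReplicates),
                        condition = conditions,
                        gene = c(genes, referenceGene),
                        stringsAsFactors = FALSE)[, 3:1]
    ct <- ifelse(rows$gene == referenceGene, 18,
                 baseCt[rows$gene] -
                   log2FoldChanges[cbind(
                     match(rows$gene, genes, nomatch = 1L),
                     match(rows$condition, conditions))] *
                   (rows$gene != referenceGene))
    ct <- ct + stats::rnorm(nrow(rows), 0, ctNoiseSd)
    data.frame(gene = rows$gene, condition = rows$condition,
               replicate = rows$replicate, ct = as.numeric(ct))
  })
}
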