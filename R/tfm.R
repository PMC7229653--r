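## Traction force microscopy: bead localization, particle-tracking
## velocimetry, displacement gridding, and the regularized Fourier-transform
## traction cytometry (FTTC) inversion with strain energy.

#' Detect fiducial beads with sub-pixel localization
#'
#' Candidate beads are local intensity maxima above a percentile cut; each
#' candidate is refined to a sub-pixel centre by the intensity-weighted
#' centroid (local background subtracted) in a window of about twice the bead
#' diameter. Duplicate detections closer than one bead radius are suppressed,
#' keeping the brighter.
#'
#' @param image 2D nonnegative image matrix.
#' @param expectedDiameterPx apparent bead diameter in pixels (> 0).
#' @param intensityPercentileCut percentile (0-100) below which maxima are
#'   ignored; default 98.
#' @param pixelSizeUm pixel size used to report physical coordinates.
#' @return A [BeadSet-class]; empty for a blank image.
#' @export
detectBeads <- function(image, expectedDiameterPx,
                        intensityPercentileCut = 98, pixelSizeUm = 1) {
  if (expectedDiameterPx <= 0) stop("expectedDiameterPx must be positive")
  stopifnot(is.matrix(image))
  cut <- stats::quantile(image, intensityPercentileCut / 100, names = FALSE)
  if (max(image) <= cut || max(image) == min(image))
    return(BeadSet(matrix(numeric(0), 0, 2), numeric(0)))
  rad <- max(1L, round(expectedDiameterPx / 2))
  isMax <- image == maxFilter(image, rad) & image > cut
  cand <- which(isMax, arr.ind = TRUE)
  if (!nrow(cand))
    return(BeadSet(matrix(numeric(0), 0, 2), numeric(0)))
  w <- max(2L, ceiling(expectedDiameterPx))  # half-width ~ diameter
  nr <- nrow(image); nc <- ncol(image)
  centers <- matrix(NA_real_, nrow(cand), 2)
  score <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rows <- max(1, r - w):min(nr, r + w)
    cols <- max(1, c - w):min(nc, c + w)
    win <- image[rows, cols]
    win <- pmax(win - min(win), 0)  # local background floor
    s <- sum(win)
    if (s <= 0) next
    centers[i, 1] <- sum(rep(cols - 1, each = length(rows)) * win) / s
    centers[i, 2] <- sum(rep(rows - 1, times = length(cols)) * win) / s
    score[i] <- s
  }
  ok <- !is.na(centers[, 1])
  centers <- centers[ok, , drop = FALSE]; score <- score[ok]
  # suppress duplicates within one radius, brighter bead wins
  ord <- order(score, decreasing = TRUE)
  keep <- logical(length(ord))
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dmin <- min(sqrt((centers[keep, 1] - centers[i, 1])^2 +
                     (centers[keep, 2] - centers[i, 2])^2))
    if (dmin >= expectedDiameterPx / 2) keep[i] <- TRUE
  }
  BeadSet(centers[keep, , drop = FALSE] * pixelSizeUm, score[keep])
}

#' Link beads between reference and deformed frames
#'
#' One-to-one matching of beads between two frames minimizing the total
#' squared displacement over all pairs closer than `maxDisplacementUm`
#' (optimal linear assignment, solved by the Hungarian method). Beads with no
#' admissible partner are dropped. Leaving a bead unmatched carries a penalty
#' of `maxDisplacementUm^2`, so any admissible match is preferred to dropping
#' the pair, and inadmissible matches are never made.
#'
#' @param ref,cur [BeadSet-class] objects from the same field of view.
#' @param maxDisplacementUm largest admissible displacement (micrometres).
#' @return data.frame with one row per matched bead: `x_um`, `y_um` (reference
#'   position), `ux_um`, `uy_um` (displacement).
#' @export
linkBeads <- function(ref, cur, maxDisplacementUm) {
  stopifnot(is(ref, "BeadSet"), is(cur, "BeadSet"), maxDisplacementUm > 0)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      ux_um = numeric(0), uy_um = numeric(0))
  n <- nrow(ref@coordsUm); m <- nrow(cur@coordsUm)
  if (n == 0 || m == 0) return(empty)
  d2 <- outer(ref@coordsUm[, 1], cur@coordsUm[, 1], "-")^2 +
    outer(ref@coordsUm[, 2], cur@coordsUm[, 2], "-")^2
  pen <- maxDisplacementUm^2
  big <- 1e6 * (pen + 1)
  # pad to (n+m) x (m+n): real-dummy = unmatched penalty, dummy-dummy = 0
  cost <- matrix(0, n + m, m + n)
  cost[seq_len(n), seq_len(m)] <- ifelse(d2 <= pen, d2, big)
  cost[seq_len(n), m + seq_len(n)] <- pen
  cost[n + seq_len(m), seq_len(m)] <- pen
  sol <- clue::solve_LSAP(cost)
  i <- seq_len(n)
  j <- as.integer(sol)[i]
  matched <- j <= m & cost[cbind(i, j)] < big
  if (!any(matched)) return(empty)
  i <- i[matched]; j <- j[matched]
  data.frame(x_um = ref@coordsUm[i, 1], y_um = ref@coordsUm[i, 2],
             ux_um = cur@coordsUm[j, 1] - ref@coordsUm[i, 1],
             uy_um = cur@coordsUm[j, 2] - ref@coordsUm[i, 2])
}

#' Remove particle-tracking outliers by the normalized median test
#'
#' Universal outlier detection for PTV displacement fields: each vector is
#' compared against the median of its k nearest neighbours; the residual,
#' normalized by the median neighbour residual plus a small floor (which
#' prevents 0/0 on noise-free fields), must not exceed `threshold` in either
#' component.
#'
#' @param displacements data.frame from [linkBeads()].
#' @param neighborhoodK number of nearest neighbours (default 8).
#' @param threshold normalized-residual cut (default 2, the conventional
#'   choice for this test).
#' @param epsilonUm residual floor in micrometres (default 0.05).
#' @return The filtered data.frame; if fewer than `neighborhoodK + 1` vectors
#'   are supplied the input is returned unchanged with a warning and attribute
#'   `filtered = FALSE`.
#' @export
filterOutliers <- function(displacements, neighborhoodK = 8, threshold = 2,
                           epsilonUm = 0.05) {
  n <- nrow(displacements)
  if (n < neighborhoodK + 1) {
    warning("too few vectors for the normalized median test; ",
            "returning input unchanged")
    attr(displacements, "filtered") <- FALSE
    return(displacements)
  }
  dx <- outer(displacements$x_um, displacements$x_um, "-")
  dy <- outer(displacements$y_um, displacements$y_um, "-")
  dist <- sqrt(dx^2 + dy^2)
  diag(dist) <- Inf
  stat <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nb <- order(dist[i, ])[seq_len(neighborhoodK)]
    for (comp in 1:2) {
      u <- displacements[[c("ux_um", "uy_um")[comp]]]
      med <- stats::median(u[nb])
      resid <- stats::median(abs(u[nb] - med))
      stat[i, comp] <- abs(u[i] - med) / (resid + epsilonUm)
    }
  }
  out <- displacements[stat[, 1] <= threshold & stat[, 2] <= threshold, ,
                       drop = FALSE]
  attr(out, "filtered") <- TRUE
  out
}

#' Interpolate scattered displacements onto a regular grid
#'
#' Scattered PTV displacement vectors are interpolated to a regular grid by
#' piecewise-linear interpolation on the Delaunay triangulation of the bead
#' positions. Grid nodes outside the convex hull are filled by nearest
#' neighbour and flagged `FALSE` in the validity mask.
#'
#' @param displacements data.frame with `x_um`, `y_um`, `ux_um`, `uy_um`.
#' @param gridSpacingUm target grid spacing (micrometres).
#' @param extentUm optional `c(xmax, ymax)`; default the data bounding box
#'   anchored at the origin.
#' @return A [DisplacementField-class].
#' @export
interpolateField <- function(displacements, gridSpacingUm, extentUm = NULL) {
  stopifnot(gridSpacingUm > 0)
  x <- displacements$x_um; y <- displacements$y_um
  if (length(x) < 3)
    stop("need at least 3 sample points for interpolation")
  cen <- cbind(x - mean(x), y - mean(y))
  if (svd(cen)$d[2] < 1e-9 * (svd(cen)$d[1] + 1e-300))
    stop("sample points are collinear; cannot triangulate")
  if (is.null(extentUm)) extentUm <- c(max(x), max(y))
  xo <- seq(0, extentUm[1], by = gridSpacingUm)
  yo <- seq(0, extentUm[2], by = gridSpacingUm)
  interpOne <- function(z) {
    g <- interp::interp(x, y, z, xo = xo, yo = yo, method = "linear",
                        duplicate = "mean")
    t(g$z)  # interp returns z[xo, yo]; we store [row=y, col=x]
  }
  ux <- interpOne(displacements$ux_um)
  uy <- interpOne(displacements$uy_um)
  valid <- !is.na(ux) & !is.na(uy)
  if (!all(valid)) {
    # fill extrapolated nodes from the nearest data point
    gx <- rep(xo, each = length(yo)); gy <- rep(yo, times = length(xo))
    bad <- which(!valid)
    for (b in bad) {
      nn <- which.min((x - gx[b])^2 + (y - gy[b])^2)
      ux[b] <- displacements$ux_um[nn]
      uy[b] <- displacements$uy_um[nn]
    }
  }
  DisplacementField(ux, uy, gridSpacingUm, validMask = valid)
}

# Discrete strain energy U = 1/2 sum(T . u) dA, tractions in Pa,
# displacements and spacing in um; 1 Pa um^3 = 1e-18 J = 1e-6 pJ.
strainEnergyQuadrature <- function(tx, ty, ux, uy, spacingUm,
                                   valid = NULL) {
  s <- tx * ux + ty * uy
  if (!is.null(valid)) s <- s[valid]
  max(0, 0.5 * sum(s) * spacingUm^2 * 1e-6)
}

# Default Tikhonov weight: lambda^2 = 1e-3 * mean diagonal of G*G over
# nonzero wavevectors.
defaultLambda <- function(G) {
  diagG2 <- G$Gxx^2 + G$Gxy^2 + G$Gxy^2 + G$Gyy^2
  sqrt(1e-3 * mean(diagG2[diagG2 > 0]) / 2)
}

#' Invert a displacement field to tractions (regularized FTTC)
#'
#' Recovers the traction field from a gridded substrate displacement field by
#' Tikhonov-regularized inversion of the Boussinesq relation in the frequency
#' domain: per wavevector, `T = (G'G + lambda^2 I)^-1 G' u`, with `G(k)` the
#' half-space Green's tensor. The displacement grids are mean-subtracted,
#' tapered at the field edges by a Tukey window (`taperFraction` of each edge)
#' and zero-padded to twice their size before the FFT: the taper and padding
#' suppress the ringing that the hard field-of-view truncation would
#' otherwise inject at the edge discontinuity. The zero-frequency traction is
#' set to zero (the half space cannot carry a net force). The strain energy
#' `U = 1/2 sum(T . u) dA` is reported in picojoules (1 Pa um^3 = 1e-6 pJ).
#'
#' @param field a [DisplacementField-class] with at least an 8 x 8 grid.
#'   Non-valid nodes contribute no information: they are reset to the field
#'   mean before inversion and excluded from the energy sum.
#' @param substrate an [ElasticSubstrate-class]; `poissonRatio >= 0.5` is
#'   rejected.
#' @param lambda Tikhonov weight (micrometres per pascal); `NULL` (default)
#'   uses `lambda^2 = 1e-3 *` mean diagonal of `G'G`. Must be nonnegative.
#' @param padFactor zero-padding factor (default 2).
#' @param taperFraction fraction of each grid edge smoothed by the Tukey
#'   window (default 0.1; 0 disables the taper).
#' @return A [TractionResult-class].
#' @export
invertFTTC <- function(field, substrate, lambda = NULL, padFactor = 2,
                       taperFraction = 0.1) {
  stopifnot(is(field, "DisplacementField"), is(substrate, "ElasticSubstrate"))
  validObject(substrate)
  d <- dim(field@ux)
  if (min(d) < 8) stop("grid must be at least 8 x 8")
  if (!is.null(lambda) && lambda < 0) stop("lambda must be nonnegative")
  ux <- field@ux; uy <- field@uy
  ux[!field@validMask] <- mean(ux[field@validMask])
  uy[!field@validMask] <- mean(uy[field@validMask])
  ux <- ux - mean(ux); uy <- uy - mean(uy)
  if (taperFraction > 0) {
    tukey <- function(n, frac) {
      w <- rep(1, n)
      m <- round(frac * n)
      if (m >= 1) {
        ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
        w[seq_len(m)] <- ramp
        w[n + 1 - seq_len(m)] <- ramp
      }
      w
    }
    W <- outer(tukey(d[1], taperFraction), tukey(d[2], taperFraction))
    ux <- ux * W; uy <- uy * W
  }
  pr <- padFactor * d[1]; pc <- padFactor * d[2]
  pux <- matrix(0, pr, pc); puy <- matrix(0, pr, pc)
  pux[seq_len(d[1]), seq_len(d[2])] <- ux
  puy[seq_len(d[1]), seq_len(d[2])] <- uy
  kg <- waveGrids(pr, pc, field@spacingUm)
  G <- greensFourier(kg$KX, kg$KY, substrate)
  if (is.null(lambda)) lambda <- defaultLambda(G)
  fux <- stats::fft(pux); fuy <- stats::fft(puy)
  # G is real symmetric, so G'G + lambda^2 I is a real 2x2 per wavevector
  a11 <- G$Gxx^2 + G$Gxy^2 + lambda^2
  a22 <- G$Gxy^2 + G$Gyy^2 + lambda^2
  a12 <- G$Gxy * (G$Gxx + G$Gyy)
  det <- a11 * a22 - a12^2
  b1 <- G$Gxx * fux + G$Gxy * fuy
  b2 <- G$Gxy * fux + G$Gyy * fuy
  ftx <- (a22 * b1 - a12 * b2) / det
  fty <- (a11 * b2 - a12 * b1) / det
  zero <- kg$KX == 0 & kg$KY == 0
  ftx[zero] <- 0; fty[zero] <- 0
  tx <- Re(stats::fft(ftx, inverse = TRUE))[seq_len(d[1]), seq_len(d[2])] /
    (pr * pc)
  ty <- Re(stats::fft(fty, inverse = TRUE))[seq_len(d[1]), seq_len(d[2])] /
    (pr * pc)
  # energy against the measured (untapered) displacements
  uPJ <- strainEnergyQuadrature(tx, ty, field@ux, field@uy,
                                field@spacingUm, field@validMask)
  new("TractionResult", tx = tx, ty = ty, magnitude = sqrt(tx^2 + ty^2),
      spacingUm = field@spacingUm, strainEnergyPJ = max(0, uPJ),
      lambda = lambda)
}

#' Strain-energy time series
#'
#' Runs [invertFTTC()] on every time point of a displacement-field series and
#' reports the strain energy over time together with its peak, the quantity
#' used to compare contractility between conditions.
#'
#' @param fields list of [DisplacementField-class] objects (>= 1).
#' @param substrate an [ElasticSubstrate-class].
#' @param lambda Tikhonov weight passed to [invertFTTC()]; `NULL` for the
#'   default heuristic computed once on the first time point (so the series is
#'   regularized consistently).
#' @param frameIntervalMin time between fields (minutes), default 30.
#' @return A list with `series` (data.frame `time_min`, `strain_energy_pJ`)
#'   and `peak_pJ`.
#' @export
strainEnergySeries <- function(fields, substrate, lambda = NULL,
                               frameIntervalMin = 30) {
  if (!length(fields)) stop("need at least one time point")
  if (is.null(lambda)) {
    d <- dim(fields[[1]]@ux)
    kg <- waveGrids(2 * d[1], 2 * d[2], fields[[1]]@spacingUm)
    lambda <- defaultLambda(greensFourier(kg$KX, kg$KY, substrate))
  }
  energies <- vapply(seq_along(fields), function(i) {
    tryCatch(strainEnergy(invertFTTC(fields[[i]], substrate, lambda)),
             error = function(e)
               stop("inversion failed at time index ", i, ": ",
                    conditionMessage(e)))
  }, numeric(1))
  series <- data.frame(time_min = (seq_along(fields) - 1) * frameIntervalMin,
                       strain_energy_pJ = energies)
  list(series = series, peak_pJ = max(energies))
}
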