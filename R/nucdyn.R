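## Nuclear dynamics: Pearson decorrelation curves of nucleus pixel
## intensities over time lags, and the three-parameter decay fit
## y(t) = (1 - alpha) + alpha exp(-t/tau) - eta.

# Integer-pixel rigid registration of `frame` to `refFrame` by FFT
# cross-correlation; returns the (dy, dx) shift maximizing the correlation.
translationShift <- function(refFrame, frame) {
  fa <- stats::fft(refFrame)
  fb <- stats::fft(frame)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  idx <- which.max(cc)
  nr <- nrow(refFrame)
  dy <- (idx - 1) %% nr
  dx <- (idx - 1) %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > ncol(refFrame) / 2) dx <- dx - ncol(refFrame)
  c(dy = dy, dx = dx)
}

shiftMatrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  srcR <- seq_len(nr) - dy
  srcC <- seq_len(nc) - dx
  okR <- srcR >= 1 & srcR <= nr
  okC <- srcC >= 1 & srcC <= nc
  out[which(okR), which(okC)] <- m[srcR[okR], srcC[okC]]
  out
}

#' Extract per-frame nucleus pixel-intensity lists
#'
#' Returns, for each frame, the intensities at the mask pixels in a fixed
#' raster order, as the columns of a matrix. The mask is taken from the first
#' frame; by default every later frame is first registered to frame 1 by
#' integer-pixel cross-correlation, so that whole-nucleus translation does not
#' masquerade as internal reorganization. With `register = FALSE` a
#' translating nucleus biases the decorrelation curve downward; the function
#' flags this (attribute `edge_gradient`) when the intensity gradient at the
#' mask edge is high relative to the interior spread.
#'
#' @param series an [ImageFrameSeries-class].
#' @param mask logical matrix, nonempty, same frame size.
#' @param register register each frame to frame 1 (default `TRUE`).
#' @return numeric matrix, `sum(mask)` rows x `nFrames` columns, with
#'   attribute `edge_gradient`.
#' @export
nucleusPixelSeries <- function(series, mask, register = TRUE) {
  stopifnot(is(series, "ImageFrameSeries"), is.logical(mask))
  if (!any(mask)) stop("mask is empty")
  if (!identical(dim(mask), dim(series@data)[1:2]))
    stop("mask and frames must share dimensions")
  nf <- nFrames(series)
  ref <- getFrame(series, 1)
  out <- matrix(NA_real_, sum(mask), nf)
  out[, 1] <- ref[mask]
  for (t in seq_len(nf)[-1]) {
    fr <- getFrame(series, t)
    if (register) {
      sh <- translationShift(ref, fr)
      if (any(sh != 0)) fr <- shiftMatrix(fr, sh["dy"], sh["dx"])
    }
    out[, t] <- fr[mask]
  }
  # edge-gradient diagnostic: mean |boundary - interior neighbour| relative
  # to the interior SD; high values indicate a mask misaligned with the
  # nucleus so motion leaks into the statistic
  inner <- mask & !boundaryOfMask(mask)
  eg <- if (any(inner) && stats::sd(ref[inner]) > 0) {
    abs(mean(ref[boundaryOfMask(mask)]) - mean(ref[inner])) /
      stats::sd(ref[inner])
  } else 0
  attr(out, "edge_gradient") <- eg
  out
}

boundaryOfMask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  er <- mask
  er[2:nr, ] <- er[2:nr, ] & mask[1:(nr - 1), ]
  er[1:(nr - 1), ] <- er[1:(nr - 1), ] & mask[2:nr, ]
  er[, 2:nc] <- er[, 2:nc] & mask[, 1:(nc - 1)]
  er[, 1:(nc - 1)] <- er[, 1:(nc - 1)] & mask[, 2:nc]
  mask & !er
}

#' Pearson decorrelation curve over time lags
#'
#' For each lag L in `1..maxLagFrames`, computes the mean over all frame pairs
#' `(t, t + L)` of the Pearson correlation between the two pixel-intensity
#' lists. Zero-variance frames are skipped with a warning; a lag that loses
#' all its pairs is dropped with a warning.
#'
#' @param pixelSeries matrix from [nucleusPixelSeries()] (pixels x frames), or
#'   an [ImageFrameSeries-class] together with `mask`.
#' @param maxLagFrames largest lag in frames; needs `maxLagFrames + 1` frames.
#' @param frameIntervalMin frame interval (minutes) used to express lags in
#'   time units; taken from the series when one is supplied.
#' @param mask logical mask, required when `pixelSeries` is a series object.
#' @return A [PCCCurve-class].
#' @export
computePCCCurve <- function(pixelSeries, maxLagFrames,
                            frameIntervalMin = 1, mask = NULL) {
  if (is(pixelSeries, "ImageFrameSeries")) {
    if (is.null(mask)) stop("mask required with an ImageFrameSeries")
    if (!is.na(frameInterval(pixelSeries)))
      frameIntervalMin <- frameInterval(pixelSeries)
    pixelSeries <- nucleusPixelSeries(pixelSeries, mask)
  }
  nf <- ncol(pixelSeries)
  if (nf < maxLagFrames + 1)
    stop("need at least maxLagFrames + 1 frames")
  sds <- apply(pixelSeries, 2, stats::sd)
  usable <- sds > 0
  if (!all(usable))
    warning(sum(!usable), " zero-variance frame(s) skipped")
  Z <- scale(pixelSeries[, usable, drop = FALSE])
  C <- crossprod(Z) / (nrow(Z) - 1)
  frameIdx <- which(usable)
  lags <- seq_len(maxLagFrames)
  pcc <- rep(NA_real_, maxLagFrames)
  npairs <- integer(maxLagFrames)
  for (L in lags) {
    pairs <- which(outer(frameIdx, frameIdx, function(a, b) b - a) == L,
                   arr.ind = TRUE)
    npairs[L] <- nrow(pairs)
    if (nrow(pairs)) pcc[L] <- mean(C[pairs])
  }
  keep <- npairs > 0
  if (!all(keep))
    warning("lag(s) ", paste(lags[!keep], collapse = ", "),
            " lost all pairs and were dropped")
  PCCCurve(lags[keep] * frameIntervalMin, pcc[keep], npairs[keep])
}

#' Mean decorrelation curve with confidence interval
#'
#' Per-lag arithmetic mean of several per-cell curves with the t-distribution
#' confidence interval of the mean. Curves with differing lag grids are
#' intersected with a warning.
#'
#' @param curves list of at least 2 [PCCCurve-class] objects.
#' @param confidence confidence level (default 0.95).
#' @return A list with `curve` (the mean [PCCCurve-class]) and `table`
#'   (data.frame `lag_min`, `mean_pcc`, `ci_low`, `ci_high`, `n_cells`).
#' @export
meanPCCCurve <- function(curves, confidence = 0.95) {
  stopifnot(length(curves) >= 2)
  lagSets <- lapply(curves, function(cv) cv@lagsMin)
  common <- Reduce(intersect, lagSets)
  if (!length(common)) stop("curves share no lags")
  if (!all(vapply(lagSets, function(l) length(l) == length(common),
                  logical(1))))
    warning("curves have mismatched lag grids; intersecting")
  common <- sort(common)
  mat <- vapply(curves, function(cv) cv@pcc[match(common, cv@lagsMin)],
                numeric(length(common)))
  mat <- matrix(mat, nrow = length(common))
  m <- rowMeans(mat)
  se <- apply(mat, 1, stats::sd) / sqrt(ncol(mat))
  tq <- stats::qt(1 - (1 - confidence) / 2, df = ncol(mat) - 1)
  list(curve = PCCCurve(common, m, rep(ncol(mat), length(common))),
       table = data.frame(lag_min = common, mean_pcc = m,
                          ci_low = m - tq * se, ci_high = m + tq * se,
                          n_cells = ncol(mat)))
}

decayModel <- function(p, t) (1 - p[1]) + p[1] * exp(-t / p[2]) - p[3]

#' Fit the three-parameter decorrelation decay model
#'
#' Fits `y(t) = (1 - alpha) + alpha exp(-t / tau) - eta` to a decorrelation
#' curve by bounded nonlinear least squares (`alpha` in \[0, 1\], `tau` in
#' (0, 10 max lag\], `eta` in \[0, 0.5\]). The fit is multi-started from the
#' moment-based initialization `alpha0 = 1 - min(y)`, `tau0 = max lag / 3`,
#' `eta0 = max(0, 1 - y(first lag))` plus three perturbed variants, keeping
#' the lowest residual sum of squares. A flat curve leaves `tau`
#' unidentifiable: the initialization value is reported and `converged` is
#' set accordingly.
#'
#' @param curve a [PCCCurve-class] with at least 4 lags and finite values.
#' @return A [DecorrelationFit-class].
#' @export
fitDecorrelation <- function(curve) {
  stopifnot(is(curve, "PCCCurve"))
  t <- curve@lagsMin; y <- curve@pcc
  if (length(t) < 4) stop("need at least 4 lags to fit 3 parameters")
  if (any(!is.finite(y))) stop("non-finite PCC values")
  lower <- c(1e-8, 1e-6, 0)
  upper <- c(1, 10 * max(t), 0.5)
  p0 <- c(alpha = min(max(1 - min(y), lower[1]), 1),
          tau = max(t) / 3,
          eta = min(max(0, 1 - y[1]), 0.5))
  starts <- list(p0)
  mult <- list(c(0.5, 0.3, 0.5), c(1.5, 3, 0.1), c(0.8, 1, 1.5))
  for (m in mult) {
    p <- pmin(pmax(p0 * m, lower), upper)
    starts <- c(starts, list(p))
  }
  rssOf <- function(p) sum((y - decayModel(p, t))^2)
  best <- NULL
  for (p in starts) {
    fit <- tryCatch({
      fo <- minpack.lm::nls.lm(
        par = p, lower = lower, upper = upper,
        fn = function(par) y - decayModel(par, t),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(par = fo$par, rss = sum(fo$fvec^2),
           converged = fo$info %in% 1:4)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      op <- stats::optim(p, rssOf, method = "L-BFGS-B",
                         lower = lower, upper = upper)
      fit <- list(par = op$par, rss = op$value,
                  converged = op$convergence == 0)
    }
    # never worse than its own start
    if (fit$rss > rssOf(p)) fit <- list(par = p, rss = rssOf(p),
                                        converged = FALSE)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  par <- unname(unlist(best$par))
  # identifiability: with alpha at (or below) noise scale tau means nothing
  identifiable <- par[1] > 1e-4
  new("DecorrelationFit",
      alpha = min(max(par[1], 0), 1),
      tauMin = par[2],
      eta = min(max(par[3], 0), 0.5),
      rss = best$rss,
      converged = isTRUE(best$converged) && identifiable)
}
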