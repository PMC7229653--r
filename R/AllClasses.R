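#' @import methods
NULL

## Central value classes. All physical quantities carry explicit units in the
## slot name (Um = micrometres, Pa = pascal, Min = minutes, PJ = picojoule).

#' Calibrated stack of single-channel image frames
#'
#' Container for a time-lapse or z-stack of one fluorescence channel, with the
#' acquisition calibration attached. Frames are stored as a numeric array
#' indexed `[row, column, frame]`; row corresponds to the image y axis and
#' column to x, both 0-based in physical coordinates: the centre of pixel
#' `(r, c)` sits at `x = (c - 1) * pixelSizeUm`, `y = (r - 1) * pixelSizeUm`.
#'
#' @slot data numeric array `[y, x, frame]`.
#' @slot pixelSizeUm lateral pixel size in micrometres.
#' @slot frameIntervalMin time between frames in minutes (`NA` for z-stacks).
#' @slot zStepUm axial step in micrometres (`NA` for time-lapses).
#' @export
setClass("ImageFrameSeries",
  representation(
    data = "array",
    pixelSizeUm = "numeric",
    frameIntervalMin = "numeric",
    zStepUm = "numeric"
  )
)

setValidity("ImageFrameSeries", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array [y, x, frame]")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@frameIntervalMin) != 1L ||
      (!is.na(object@frameIntervalMin) && object@frameIntervalMin <= 0))
    msg <- c(msg, "frameIntervalMin must be positive or NA")
  if (length(object@zStepUm) != 1L ||
      (!is.na(object@zStepUm) && object@zStepUm <= 0))
    msg <- c(msg, "zStepUm must be positive or NA")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageFrameSeries
#'
#' @param data a numeric matrix (single frame) or 3D array `[y, x, frame]`,
#'   or a list of equally sized matrices.
#' @param pixelSizeUm lateral pixel size (micrometres).
#' @param frameIntervalMin frame interval (minutes), `NA` if not a time-lapse.
#' @param zStepUm z step (micrometres), `NA` if not a z-stack.
#' @return An [ImageFrameSeries-class] object.
#' @examples
#' s <- ImageFrameSeries(array(runif(32), c(4, 4, 2)), pixelSizeUm = 0.42)
#' nFrames(s)
#' @export
ImageFrameSeries <- function(data, pixelSizeUm = 1,
                             frameIntervalMin = NA_real_,
                             zStepUm = NA_real_) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L)
      stop("all frames must share dimensions")
    data <- array(unlist(data, use.names = FALSE),
                  c(dims[[1]], length(data)))
  }
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("ImageFrameSeries", data = data,
      pixelSizeUm = as.numeric(pixelSizeUm),
      frameIntervalMin = as.numeric(frameIntervalMin),
      zStepUm = as.numeric(zStepUm))
}

#' Linear-elastic substrate description
#'
#' Material parameters of the elastic half-space on (or in) which the cells
#' exert traction: Young's modulus and Poisson's ratio. The Boussinesq
#' solution diverges for an incompressible medium, so `poissonRatio` must be
#' strictly below 0.5.
#'
#' @slot youngModulusPa Young's modulus in pascals.
#' @slot poissonRatio Poisson's ratio, in `[0, 0.5)`.
#' @export
setClass("ElasticSubstrate",
  representation(youngModulusPa = "numeric", poissonRatio = "numeric")
)

setValidity("ElasticSubstrate", function(object) {
  msg <- NULL
  if (length(object@youngModulusPa) != 1L || object@youngModulusPa <= 0)
    msg <- c(msg, "youngModulusPa must be a single positive number")
  if (length(object@poissonRatio) != 1L || object@poissonRatio < 0 ||
      object@poissonRatio >= 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5)")
  if (is.null(msg)) TRUE else msg
})

#' @param youngModulusPa Young's modulus (Pa).
#' @param poissonRatio Poisson's ratio in `[0, 0.5)`.
#' @rdname ElasticSubstrate-class
#' @examples
#' ElasticSubstrate(1000, 0.45)
#' @export
ElasticSubstrate <- function(youngModulusPa, poissonRatio) {
  new("ElasticSubstrate", youngModulusPa = as.numeric(youngModulusPa),
      poissonRatio = as.numeric(poissonRatio))
}

#' Ground-truth traction field on a regular grid
#'
#' A known traction stress field (x and y components, Pa) on a regular grid,
#' together with the substrate it acts on. Used by the synthetic-data
#' generators as the quantity the inversion is meant to recover. A half-space
#' inversion cannot represent a field with net force, so the components must
#' sum to zero (the constructor balances them by subtracting the mean unless
#' told otherwise).
#'
#' @slot tx,ty traction components (Pa), matrices of equal dimension.
#' @slot spacingUm grid spacing in micrometres.
#' @slot substrate an [ElasticSubstrate-class].
#' @export
setClass("TractionTruth",
  representation(tx = "matrix", ty = "matrix", spacingUm = "numeric",
                 substrate = "ElasticSubstrate")
)

setValidity("TractionTruth", function(object) {
  msg <- NULL
  if (!identical(dim(object@tx), dim(object@ty)))
    msg <- c(msg, "tx and ty must share dimensions")
  if (length(object@spacingUm) != 1L || object@spacingUm <= 0)
    msg <- c(msg, "spacingUm must be a single positive number")
  scale <- mean(sqrt(object@tx^2 + object@ty^2))
  if (scale > 0) {
    rel <- max(abs(sum(object@tx)), abs(sum(object@ty))) /
      (scale * length(object@tx))
    if (rel > 1e-10)
      msg <- c(msg, "net force must vanish (|sum T| / (mean |T| * n) > 1e-10)")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param tx,ty traction component matrices (Pa).
#' @param spacingUm grid spacing (micrometres).
#' @param substrate an [ElasticSubstrate-class].
#' @param balance subtract the mean from each component so the net force is
#'   exactly zero (default `TRUE`).
#' @rdname TractionTruth-class
#' @export
TractionTruth <- function(tx, ty, spacingUm, substrate, balance = TRUE) {
  if (balance) {
    tx <- tx - mean(tx)
    ty <- ty - mean(ty)
  }
  new("TractionTruth", tx = tx, ty = ty, spacingUm = as.numeric(spacingUm),
      substrate = substrate)
}

#' Set of localized fiducial beads
#'
#' Sub-pixel bead centres detected in one frame, in physical units, with a
#' per-bead quality score (integrated spot intensity).
#'
#' @slot coordsUm n x 2 matrix of (x, y) positions in micrometres.
#' @slot quality numeric vector of detection scores, one per bead.
#' @export
setClass("BeadSet",
  representation(coordsUm = "matrix", quality = "numeric")
)

setValidity("BeadSet", function(object) {
  msg <- NULL
  if (ncol(object@coordsUm) != 2L)
    msg <- c(msg, "coordsUm must have two columns (x_um, y_um)")
  if (length(object@quality) != nrow(object@coordsUm))
    msg <- c(msg, "quality must have one entry per bead")
  if (is.null(msg)) TRUE else msg
})

#' @param coordsUm n x 2 matrix of (x, y) bead positions (micrometres).
#' @param quality per-bead score; defaults to 1 for each bead.
#' @rdname BeadSet-class
#' @export
BeadSet <- function(coordsUm, quality = rep(1, nrow(coordsUm))) {
  coordsUm <- matrix(as.numeric(coordsUm), ncol = 2,
                     dimnames = list(NULL, c("x_um", "y_um")))
  new("BeadSet", coordsUm = coordsUm, quality = as.numeric(quality))
}

#' Substrate displacement field on a regular grid
#'
#' Gridded displacement components (micrometres) with a validity mask: nodes
#' outside the convex hull of the measured beads are filled by nearest
#' neighbour and flagged `FALSE` so that downstream consumers can exclude
#' them. Node `(r, c)` sits at `originUm + ((c - 1), (r - 1)) * spacingUm`.
#'
#' @slot ux,uy displacement components (micrometres).
#' @slot spacingUm grid spacing in micrometres.
#' @slot validMask logical matrix; `TRUE` where the node is interpolated from
#'   data rather than extrapolated.
#' @slot originUm numeric length 2, physical (x, y) of node (1, 1).
#' @export
setClass("DisplacementField",
  representation(ux = "matrix", uy = "matrix", spacingUm = "numeric",
                 validMask = "matrix", originUm = "numeric")
)

setValidity("DisplacementField", function(object) {
  msg <- NULL
  if (!identical(dim(object@ux), dim(object@uy)) ||
      !identical(dim(object@ux), dim(object@validMask)))
    msg <- c(msg, "ux, uy and validMask must share dimensions")
  if (length(object@spacingUm) != 1L || object@spacingUm <= 0)
    msg <- c(msg, "spacingUm must be a single positive number")
  if (length(object@originUm) != 2L)
    msg <- c(msg, "originUm must have length 2")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  if (is.null(msg)) TRUE else msg
})

#' @param ux,uy displacement component matrices (micrometres).
#' @param spacingUm grid spacing (micrometres).
#' @param validMask logical matrix (default all `TRUE`).
#' @param originUm physical position of node (1,1), default `c(0, 0)`.
#' @rdname DisplacementField-class
#' @export
DisplacementField <- function(ux, uy, spacingUm,
                              validMask = NULL, originUm = c(0, 0)) {
  if (is.null(validMask))
    validMask <- matrix(TRUE, nrow(ux), ncol(ux))
  new("DisplacementField", ux = ux, uy = uy,
      spacingUm = as.numeric(spacingUm), validMask = validMask,
      originUm = as.numeric(originUm))
}

#' Recovered traction field with strain energy
#'
#' Result of the regularized Fourier-transform traction cytometry inversion:
#' traction components and magnitude (Pa) on the displacement grid, the total
#' strain energy stored in the substrate (picojoules), and the Tikhonov
#' regularization weight used.
#'
#' @slot tx,ty,magnitude traction grids (Pa); `magnitude = sqrt(tx^2 + ty^2)`.
#' @slot spacingUm grid spacing (micrometres).
#' @slot strainEnergyPJ strain energy `U = 1/2 sum(T . u) dA` in picojoules.
#' @slot lambda Tikhonov regularization weight (same units as the Fourier
#'   Green's tensor, micrometres per pascal).
#' @export
setClass("TractionResult",
  representation(tx = "matrix", ty = "matrix", magnitude = "matrix",
                 spacingUm = "numeric", strainEnergyPJ = "numeric",
                 lambda = "numeric")
)

setValidity("TractionResult", function(object) {
  msg <- NULL
  if (!identical(dim(object@tx), dim(object@ty)) ||
      !identical(dim(object@tx), dim(object@magnitude)))
    msg <- c(msg, "tx, ty, magnitude must share dimensions")
  if (max(abs(object@magnitude - sqrt(object@tx^2 + object@ty^2))) >
      1e-8 * (1 + max(object@magnitude)))
    msg <- c(msg, "magnitude must equal sqrt(tx^2 + ty^2)")
  if (object@strainEnergyPJ < 0)
    msg <- c(msg, "strainEnergyPJ must be nonnegative")
  if (object@lambda < 0)
    msg <- c(msg, "lambda must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Pearson decorrelation curve of a nucleus
#'
#' Mean Pearson correlation between the pixel-intensity lists of the same
#' nucleus at all frame pairs separated by each time lag. Lag zero is excluded
#' by construction (it is identically one).
#'
#' @slot lagsMin increasing positive time lags (minutes).
#' @slot pcc Pearson correlation at each lag, in `[-1, 1]`.
#' @slot nPairs number of frame pairs averaged at each lag.
#' @export
setClass("PCCCurve",
  representation(lagsMin = "numeric", pcc = "numeric", nPairs = "integer")
)

setValidity("PCCCurve", function(object) {
  msg <- NULL
  n <- length(object@lagsMin)
  if (length(object@pcc) != n || length(object@nPairs) != n)
    msg <- c(msg, "lagsMin, pcc and nPairs must share length")
  if (n && (any(object@lagsMin <= 0) || is.unsorted(object@lagsMin,
                                                    strictly = TRUE)))
    msg <- c(msg, "lagsMin must be strictly increasing and positive")
  bad <- !is.na(object@pcc) &
    (object@pcc < -1 - 1e-12 | object@pcc > 1 + 1e-12)
  if (n && any(bad))
    msg <- c(msg, "pcc values must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @param lagsMin time lags in minutes.
#' @param pcc Pearson correlations, one per lag.
#' @param nPairs frame pairs per lag.
#' @rdname PCCCurve-class
#' @export
PCCCurve <- function(lagsMin, pcc, nPairs = rep(1L, length(lagsMin))) {
  new("PCCCurve", lagsMin = as.numeric(lagsMin),
      pcc = pmin(1, pmax(-1, as.numeric(pcc))), nPairs = as.integer(nPairs))
}

#' Three-parameter fit of a decorrelation curve
#'
#' Parameters of the decay model `y(t) = (1 - alpha) + alpha * exp(-t / tau)
#' - eta` fitted to a [PCCCurve-class]: `alpha` is the drop rate (fraction of
#' correlation ultimately lost), `tau` the time constant in minutes, and
#' `eta` a lag-independent noise offset.
#'
#' @slot alpha drop rate in `[0, 1]`.
#' @slot tauMin time constant (minutes), positive.
#' @slot eta noise offset in `[0, 0.5]`.
#' @slot rss residual sum of squares of the fit.
#' @slot converged whether the optimizer reported convergence and the
#'   parameters are identifiable.
#' @export
setClass("DecorrelationFit",
  representation(alpha = "numeric", tauMin = "numeric", eta = "numeric",
                 rss = "numeric", converged = "logical")
)

setValidity("DecorrelationFit", function(object) {
  msg <- NULL
  if (object@alpha < -1e-9 || object@alpha > 1 + 1e-9)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@tauMin <= 0)
    msg <- c(msg, "tauMin must be positive")
  if (object@eta < -1e-9 || object@eta > 0.5 + 1e-9)
    msg <- c(msg, "eta must lie in [0, 0.5]")
  if (object@rss < 0)
    msg <- c(msg, "rss must be nonnegative")
  if (is.null(msg)) TRUE else msg
})
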