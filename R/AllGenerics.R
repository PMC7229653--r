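#' Number of frames in a series
#' @param x an [ImageFrameSeries-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Lateral pixel size in micrometres
#' @param x an object carrying a pixel calibration.
#' @return numeric pixel size (micrometres).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Frame interval in minutes
#' @param x an [ImageFrameSeries-class].
#' @return numeric frame interval (minutes), possibly `NA`.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Extract one frame as a matrix
#' @param x an [ImageFrameSeries-class].
#' @param i frame index.
#' @return numeric matrix `[y, x]`.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Grid spacing in micrometres
#' @param x a gridded object ([DisplacementField-class],
#'   [TractionResult-class] or [TractionTruth-class]).
#' @return numeric spacing (micrometres).
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' Traction components
#' @param x a [TractionResult-class] or [TractionTruth-class].
#' @return named list with matrices `tx` and `ty` (Pa).
#' @export
setGeneric("tractions", function(x) standardGeneric("tractions"))

#' Displacement components
#' @param x a [DisplacementField-class].
#' @return named list with matrices `ux` and `uy` (micrometres) and the
#'   logical `valid` mask.
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' Strain energy in picojoules
#' @param x a [TractionResult-class].
#' @return numeric strain energy (pJ).
#' @export
setGeneric("strainEnergy", function(x) standardGeneric("strainEnergy"))

#' Bead coordinates in micrometres
#' @param x a [BeadSet-class].
#' @return n x 2 matrix of (x, y) positions (micrometres).
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))

#' Fitted parameters of a decorrelation fit
#' @param x a [DecorrelationFit-class].
#' @return named numeric vector `c(alpha, tau_min, eta, rss)`.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' Curve data of a PCC curve
#' @param x a [PCCCurve-class].
#' @return data.frame with columns `lag_min`, `pcc`, `n_pairs`.
#' @export
setGeneric("curveData", function(x) standardGeneric("curveData"))
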