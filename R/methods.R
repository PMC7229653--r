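#' @rdname nFrames
#' @aliases nFrames,ImageFrameSeries-method
setMethod("nFrames", "ImageFrameSeries", function(x) dim(x@data)[3L])

#' @rdname pixelSize
#' @aliases pixelSize,ImageFrameSeries-method
setMethod("pixelSize", "ImageFrameSeries", function(x) x@pixelSizeUm)

#' @rdname frameInterval
#' @aliases frameInterval,ImageFrameSeries-method
setMethod("frameInterval", "ImageFrameSeries", function(x) x@frameIntervalMin)

#' @rdname getFrame
#' @aliases getFrame,ImageFrameSeries-method
setMethod("getFrame", "ImageFrameSeries", function(x, i) {
  stopifnot(i >= 1L, i <= dim(x@data)[3L])
  x@data[, , i, drop = TRUE]
})

#' @rdname gridSpacing
#' @aliases gridSpacing,DisplacementField-method
setMethod("gridSpacing", "DisplacementField", function(x) x@spacingUm)

#' @rdname gridSpacing
#' @aliases gridSpacing,TractionResult-method
setMethod("gridSpacing", "TractionResult", function(x) x@spacingUm)

#' @rdname gridSpacing
#' @aliases gridSpacing,TractionTruth-method
setMethod("gridSpacing", "TractionTruth", function(x) x@spacingUm)

#' @rdname tractions
#' @aliases tractions,TractionResult-method
setMethod("tractions", "TractionResult",
          function(x) list(tx = x@tx, ty = x@ty))

#' @rdname tractions
#' @aliases tractions,TractionTruth-method
setMethod("tractions", "TractionTruth",
          function(x) list(tx = x@tx, ty = x@ty))

#' @rdname displacements
#' @aliases displacements,DisplacementField-method
setMethod("displacements", "DisplacementField",
          function(x) list(ux = x@ux, uy = x@uy, valid = x@validMask))

#' @rdname strainEnergy
#' @aliases strainEnergy,TractionResult-method
setMethod("strainEnergy", "TractionResult", function(x) x@strainEnergyPJ)

#' @rdname beadCoords
#' @aliases beadCoords,BeadSet-method
setMethod("beadCoords", "BeadSet", function(x) x@coordsUm)

#' @rdname fitParams
#' @aliases fitParams,DecorrelationFit-method
setMethod("fitParams", "DecorrelationFit", function(x)
  c(alpha = x@alpha, tau_min = x@tauMin, eta = x@eta, rss = x@rss))

#' @rdname curveData
#' @aliases curveData,PCCCurve-method
setMethod("curveData", "PCCCurve", function(x)
  data.frame(lag_min = x@lagsMin, pcc = x@pcc, n_pairs = x@nPairs))

#' @importFrom utils head
setMethod("show", "ImageFrameSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageFrameSeries: %d x %d px, %d frame(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size %.4g um", object@pixelSizeUm))
  if (!is.na(object@frameIntervalMin))
    cat(sprintf(", frame interval %.4g min", object@frameIntervalMin))
  if (!is.na(object@zStepUm))
    cat(sprintf(", z step %.4g um", object@zStepUm))
  cat("\n")
})

setMethod("show", "ElasticSubstrate", function(object) {
  cat(sprintf("ElasticSubstrate: E = %.4g Pa, nu = %.3g\n",
              object@youngModulusPa, object@poissonRatio))
})

setMethod("show", "TractionTruth", function(object) {
  d <- dim(object@tx)
  cat(sprintf("TractionTruth: %d x %d grid, spacing %.4g um\n",
              d[1], d[2], object@spacingUm))
  cat(sprintf("  max |T| = %.4g Pa, net force ~ %.2e\n",
              max(sqrt(object@tx^2 + object@ty^2)),
              max(abs(sum(object@tx)), abs(sum(object@ty)))))
})

setMethod("show", "BeadSet", function(object) {
  cat(sprintf("BeadSet: %d bead(s)\n", nrow(object@coordsUm)))
  if (nrow(object@coordsUm))
    print(head(cbind(object@coordsUm, quality = object@quality), 4))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@ux)
  cat(sprintf("DisplacementField: %d x %d grid, spacing %.4g um, %d%% valid\n",
              d[1], d[2], object@spacingUm,
              round(100 * mean(object@validMask))))
  cat(sprintf("  max |u| = %.4g um\n",
              max(sqrt(object@ux^2 + object@uy^2))))
})

setMethod("show", "TractionResult", function(object) {
  d <- dim(object@tx)
  cat(sprintf("TractionResult: %d x %d grid, spacing %.4g um\n",
              d[1], d[2], object@spacingUm))
  cat(sprintf("  max |T| = %.4g Pa, strain energy %.4g pJ, lambda %.3g\n",
              max(object@magnitude), object@strainEnergyPJ, object@lambda))
})

setMethod("show", "PCCCurve", function(object) {
  cat(sprintf("PCCCurve: %d lag(s), %.4g to %.4g min\n",
              length(object@lagsMin),
              if (length(object@lagsMin)) min(object@lagsMin) else NA,
              if (length(object@lagsMin)) max(object@lagsMin) else NA))
  if (length(object@pcc))
    cat(sprintf("  pcc range [%.3f, %.3f]\n",
                min(object@pcc), max(object@pcc)))
})

setMethod("show", "DecorrelationFit", function(object) {
  cat(sprintf(
    "DecorrelationFit: alpha = %.4f, tau = %.3f min, eta = %.4f\n",
    object@alpha, object@tauMin, object@eta))
  cat(sprintf("  rss = %.4g, converged = %s\n",
              object@rss, object@converged))
})
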