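#' @include AllClasses.R
NULL

#' Accessors for gating-analysis objects
#'
#' Small accessor generics in place of direct slot access: `constructId`,
#' `protocolKind`, `xValues` (swept variable), `peakMatrix` (replicate-by-x
#' matrix), `seriesMeans` (per-point replicate means), `nReplicates`,
#' `temperatureK`, `midpoint` (V1/2 or Va1/2), `slopeFactor`,
#' `effectiveValence`, `residualRMS`, `deltaG`, `standardError`, `isCoupled`.
#'
#' @param object an object of one of the classes in this package.
#' @return the slot value; see each class for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("constructId", function(object) standardGeneric("constructId"))
#' @rdname accessors
#' @export
setGeneric("protocolKind", function(object) standardGeneric("protocolKind"))
#' @rdname accessors
#' @export
setGeneric("xValues", function(object) standardGeneric("xValues"))
#' @rdname accessors
#' @export
setGeneric("peakMatrix", function(object) standardGeneric("peakMatrix"))
#' @rdname accessors
#' @export
setGeneric("seriesMeans", function(object) standardGeneric("seriesMeans"))
#' @rdname accessors
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))
#' @rdname accessors
#' @export
setGeneric("temperatureK", function(object) standardGeneric("temperatureK"))
#' @rdname accessors
#' @export
setGeneric("midpoint", function(object) standardGeneric("midpoint"))
#' @rdname accessors
#' @export
setGeneric("slopeFactor", function(object) standardGeneric("slopeFactor"))
#' @rdname accessors
#' @export
setGeneric("effectiveValence",
           function(object) standardGeneric("effectiveValence"))
#' @rdname accessors
#' @export
setGeneric("residualRMS", function(object) standardGeneric("residualRMS"))
#' @rdname accessors
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))
#' @rdname accessors
#' @export
setGeneric("standardError", function(object) standardGeneric("standardError"))
#' @rdname accessors
#' @export
setGeneric("isCoupled", function(object) standardGeneric("isCoupled"))
#' @rdname accessors
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))

## PeakSeries -----------------------------------------------------------------

#' @rdname accessors
setMethod("constructId", "PeakSeries", function(object) object@constructId)
#' @rdname accessors
setMethod("protocolKind", "PeakSeries", function(object) object@protocolKind)
#' @rdname accessors
setMethod("xValues", "PeakSeries", function(object) object@x)
#' @rdname accessors
setMethod("peakMatrix", "PeakSeries", function(object) object@y)
#' @rdname accessors
setMethod("seriesMeans", "PeakSeries", function(object) colMeans(object@y))
#' @rdname accessors
setMethod("nReplicates", "PeakSeries", function(object) nrow(object@y))
#' @rdname accessors
setMethod("temperatureK", "PeakSeries", function(object) object@temperature)

setMethod("show", "PeakSeries", function(object) {
  cat(sprintf("PeakSeries '%s' (%s): %d x-values, %d replicate(s), %.2f K\n",
              object@constructId, object@protocolKind, length(object@x),
              nrow(object@y), object@temperature))
  cat("  x range:", paste(signif(range(object@x), 4), collapse = " .. "),
      if (object@protocolKind == "recovery") "ms\n" else "mV\n")
})

## VoltageProtocol ------------------------------------------------------------

#' @rdname accessors
setMethod("protocolKind", "VoltageProtocol", function(object) object@kind)

setMethod("show", "VoltageProtocol", function(object) {
  cat(sprintf("VoltageProtocol (%s): %d segment(s), sweeping %s of segment %d\n",
              object@kind, nrow(object@segments), object@sweepDimension,
              object@sweptSegment))
  cat(sprintf("  holding %.0f mV; %d sweep values in [%.4g, %.4g]\n",
              object@holdingVoltage, length(object@sweepValues),
              min(object@sweepValues), max(object@sweepValues)))
})

## GatingScheme ---------------------------------------------------------------

setMethod("show", "GatingScheme", function(object) {
  cat(sprintf("GatingScheme: %s (conducting: %s)\n",
              paste(object@stateLabels, collapse = " - "),
              object@conductingState))
  cat(sprintf("  %d transitions; reversal %+.0f mV\n",
              nrow(object@rates), object@reversalPotential))
})

## Fits -----------------------------------------------------------------------

#' @rdname accessors
setMethod("midpoint", "BoltzmannFit", function(object) object@v12)
#' @rdname accessors
setMethod("slopeFactor", "BoltzmannFit", function(object) object@slope)
#' @rdname accessors
setMethod("effectiveValence", "BoltzmannFit", function(object) object@z)
#' @rdname accessors
setMethod("residualRMS", "BoltzmannFit", function(object) object@residualRMS)
#' @rdname accessors
setMethod("temperatureK", "BoltzmannFit", function(object) object@temperature)
#' @rdname accessors
setMethod("fitFlags", "BoltzmannFit", function(object) object@flags)

#' @describeIn accessors named parameter vector of a Boltzmann fit.
#' @export
setMethod("coef", "BoltzmannFit", function(object, ...) {
  c(v12 = object@v12, slope = object@slope, z = object@z)
})

setMethod("show", "BoltzmannFit", function(object) {
  cat(sprintf("BoltzmannFit: V1/2 = %.2f +/- %.2f mV, k = %.2f +/- %.2f mV\n",
              object@v12, object@v12SE, object@slope, object@slopeSE))
  cat(sprintf("  z = %.3f +/- %.3f at %.2f K; RMS %.3g over %d points\n",
              object@z, object@zSE, object@temperature,
              object@residualRMS, object@nPoints))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("residualRMS", "RecoveryFit", function(object) object@residualRMS)
#' @rdname accessors
setMethod("fitFlags", "RecoveryFit", function(object) object@flags)

#' @describeIn accessors named parameter vector of a recovery fit.
#' @export
setMethod("coef", "RecoveryFit", function(object, ...) {
  n <- object@nComponents
  out <- c(object@amplitudes, object@tau, object@offset)
  names(out) <- c(paste0("A", seq_len(n)), paste0("tau", seq_len(n)), "C")
  out
})

setMethod("show", "RecoveryFit", function(object) {
  cat(sprintf("RecoveryFit (%d components): C = %.3f\n",
              object@nComponents, object@offset))
  for (i in seq_len(object@nComponents))
    cat(sprintf("  A%d = %.3f +/- %.3f, tau%d = %.4g +/- %.3g ms\n",
                i, object@amplitudes[i], object@amplitudeSE[i],
                i, object@tau[i], object@tauSE[i]))
  cat(sprintf("  RMS %.3g over %d points\n", object@residualRMS,
              object@nPoints))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("midpoint", "ActivationFit", function(object) object@va12)
#' @rdname accessors
setMethod("slopeFactor", "ActivationFit", function(object) object@slope)
#' @rdname accessors
setMethod("residualRMS", "ActivationFit", function(object) object@residualRMS)
#' @rdname accessors
setMethod("fitFlags", "ActivationFit", function(object) object@flags)

#' @describeIn accessors named parameter vector of an activation fit.
#' @export
setMethod("coef", "ActivationFit", function(object, ...) {
  c(gMax = object@gMax, vRev = object@vRev, va12 = object@va12,
    slope = object@slope)
})

setMethod("show", "ActivationFit", function(object) {
  cat(sprintf("ActivationFit: Va1/2 = %.2f +/- %.2f mV, K = %.2f +/- %.2f mV\n",
              object@va12, object@va12SE, object@slope, object@slopeSE))
  cat(sprintf("  Gmax = %.4g, Vrev = %.1f mV; RMS %.3g over %d points\n",
              object@gMax, object@vRev, object@residualRMS, object@nPoints))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

## Energetics -----------------------------------------------------------------

#' @rdname accessors
setMethod("constructId", "FreeEnergy", function(object) object@constructId)
#' @rdname accessors
setMethod("deltaG", "FreeEnergy", function(object) object@deltaG)
#' @rdname accessors
setMethod("standardError", "FreeEnergy", function(object) object@se)
#' @rdname accessors
setMethod("temperatureK", "FreeEnergy", function(object) object@temperature)

setMethod("show", "FreeEnergy", function(object) {
  cat(sprintf("FreeEnergy '%s': dG = %.3f +/- %.3f kcal/mol at %.2f K\n",
              object@constructId, object@deltaG, object@se,
              object@temperature))
})

#' @rdname accessors
setMethod("deltaG", "CycleResult", function(object) object@deltaDeltaG)
#' @rdname accessors
setMethod("standardError", "CycleResult", function(object) object@se)
#' @rdname accessors
setMethod("isCoupled", "CycleResult", function(object) object@coupled)

setMethod("show", "CycleResult", function(object) {
  cat(sprintf("CycleResult [%s x %s]: ddG = %.3f +/- %.3f kcal/mol (%s SE)\n",
              object@ids[["mut1"]], object@ids[["mut2"]],
              object@deltaDeltaG, object@se, object@seMode))
  cat(sprintf("  |ddG| %s %.1f kcal/mol -> %s\n",
              if (object@coupled) ">" else "<=", object@threshold,
              if (object@coupled) "coupled" else "not coupled"))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: R = %.3f, two-tailed P = %.3g, n = %d\n",
              object@r, object@p, object@nUsed))
  if (length(object@excluded))
    cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
})
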