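#' @include propagate.R
NULL

#' Simulate a noiseless peak-current series from a Markov scheme
#'
#' Runs a protocol through [propagateScheme()] sweep by sweep; segments
#' before the test pulse are collapsed to a single exact matrix-exponential
#' step, the final (test) segment is sampled densely. The peak is the
#' extremum of `occupancy(open) * conductance * (V - Vrev)` after the blank
#' window (capacitive-transient blanking), sign preserved; the series is
#' then normalized to its largest-magnitude peak.
#'
#' @param scheme a [GatingScheme-class].
#' @param protocol a [VoltageProtocol-class] whose final segment is the test
#'   pulse.
#' @param blankMs initial portion of the test pulse excluded from peak
#'   detection, ms.
#' @param temperature recording temperature stored on the series, K.
#' @param constructId construct name stored on the series.
#' @return a single-replicate [PeakSeries-class].
#' @export
simulatePeakSeries <- function(scheme, protocol, blankMs = 0.3,
                               temperature = 291.15,
                               constructId = "scheme") {
  validObject(scheme); validObject(protocol)
  p0 <- stationaryOccupancy(scheme, protocol@holdingVoltage)
  dt <- protocol@sampleInterval
  iOpen <- match(scheme@conductingState, scheme@stateLabels)
  nSeg <- nrow(protocol@segments)
  peaks <- vapply(protocol@sweepValues, function(sv) {
    seg <- .realizeSegments(protocol, sv)
    p <- as.numeric(p0)
    if (nSeg > 1L) {
      for (i in seq_len(nSeg - 1L)) {
        p <- .propagateEnd(p, rateMatrix(scheme, seg$voltage[i]),
                           seg$duration[i])
      }
    }
    vTest <- seg$voltage[nSeg]
    res <- .propagateDense(p, rateMatrix(scheme, vTest),
                           seg$duration[nSeg], dt)
    keep <- res$times > blankMs
    if (!any(keep))
      stop("test pulse has no samples after the blank window")
    current <- res$occupancy[keep, iOpen] * scheme@conductance *
      (vTest - scheme@reversalPotential)
    current[which.max(abs(current))]
  }, numeric(1))
  ref <- peaks[which.max(abs(peaks))]
  if (abs(ref) == 0)
    stop("all test-pulse currents are zero; series cannot be normalized")
  new("PeakSeries",
      constructId = constructId, protocolKind = protocol@kind,
      x = protocol@sweepValues,
      y = matrix(peaks / ref, nrow = 1),
      temperature = temperature)
}
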