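#' @include AllClasses.R
NULL

#' Extract the peak current from one sweep
#'
#' Extremum of the current after the blank window (the initial stretch of
#' the test pulse contaminated by the capacitive transient). Inward
#' (negative) currents are returned with their sign preserved.
#'
#' @param samples data.frame with columns `time` (ms, strictly increasing)
#'   and `current` (arbitrary units).
#' @param blankMs blank window, ms.
#' @param sweepId label used in error messages.
#' @return the signed peak amplitude.
#' @export
extractPeak <- function(samples, blankMs = 0.3, sweepId = "sweep") {
  stopifnot(all(c("time", "current") %in% names(samples)))
  if (is.unsorted(samples$time, strictly = TRUE))
    stop(sprintf("%s: sample times must be strictly increasing", sweepId))
  keep <- samples$time > blankMs
  if (!any(keep))
    stop(sprintf("%s: no samples after the %g ms blank window",
                 sweepId, blankMs))
  cur <- samples$current[keep]
  cur[which.max(abs(cur))]
}

#' Normalize a vector of peak currents into a PeakSeries
#'
#' Divides by a signed reference so that normalized availability is
#' positive for inward currents. `mode = "max"` uses the largest-magnitude
#' peak; `mode = "reference_x"` uses the peak at a designated swept value
#' (for steady-state inactivation, conventionally the most hyperpolarized
#' conditioning voltage, where availability is ~1, so that noise at the
#' series maximum does not bias the reference).
#'
#' @param peaks signed peak currents, one per swept value.
#' @param x swept values (strictly monotone).
#' @param mode `"reference_x"` or `"max"`.
#' @param referenceX the designated swept value for `mode = "reference_x"`;
#'   defaults to the most hyperpolarized (smallest) `x`.
#' @param protocolKind stored on the resulting series.
#' @param constructId construct name.
#' @param temperature K.
#' @return a single-replicate [PeakSeries-class].
#' @export
normalizeSeries <- function(peaks, x, mode = c("reference_x", "max"),
                            referenceX = NULL, protocolKind = "ssi",
                            constructId = "series", temperature = 291.15) {
  mode <- match.arg(mode)
  stopifnot(length(peaks) == length(x))
  ref <- switch(mode,
    max = peaks[which.max(abs(peaks))],
    reference_x = {
      if (is.null(referenceX)) referenceX <- x[which.min(x)]
      i <- which(x == referenceX)
      if (length(i) != 1L)
        stop("referenceX must match exactly one swept value")
      peaks[i]
    })
  if (!is.finite(ref) || abs(ref) == 0)
    stop("normalization reference is zero or non-finite")
  new("PeakSeries",
      constructId = constructId, protocolKind = protocolKind,
      x = as.numeric(x), y = matrix(peaks / ref, nrow = 1),
      temperature = temperature)
}
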