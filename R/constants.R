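## Physical constants (CODATA). Energies are reported in kcal/mol because the
## conventional 1 kcal/mol direct-coupling criterion fixes that unit.

.GAS_CONSTANT <- 8.31446261815324   # J mol^-1 K^-1
.FARADAY <- 96485.33212             # C mol^-1
.FARADAY_KCAL <- 23.061             # kcal mol^-1 V^-1

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature Absolute temperature in kelvin.
#' @return RT/F in mV (about 25.09 mV at 291.15 K, the 18 degree C bath used
#'   for oocyte recordings).
#' @export
rtfMillivolts <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1000 * .GAS_CONSTANT * temperature / .FARADAY
}
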