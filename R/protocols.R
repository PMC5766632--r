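#' @include AllClasses.R
NULL

#' Construct a voltage protocol
#'
#' General constructor; most users will want the canned protocols
#' [ssiProtocol()], [recoveryProtocol()] and [activationProtocol()], which
#' encode the conventional two-electrode / patch-clamp pulse trains: 50 ms
#' conditioning pulses followed by a 10 ms test pulse for steady-state
#' inactivation, a 100 ms or 1 s prepulse followed by a variable recovery
#' interval and a test pulse for recovery, and 20 ms steps from -100 to
#' +70 mV for activation.
#'
#' @param segments data.frame with columns `voltage` (mV), `duration` (ms).
#' @param sweptSegment index of the swept segment.
#' @param sweepValues strictly monotone numeric vector of swept voltages (mV)
#'   or durations (ms).
#' @param sweepDimension `"voltage"` or `"duration"`.
#' @param holdingVoltage resting potential, mV.
#' @param sampleInterval sampling step, ms.
#' @param kind protocol kind label.
#' @return a [VoltageProtocol-class] object.
#' @export
VoltageProtocol <- function(segments, sweptSegment, sweepValues,
                            sweepDimension = c("voltage", "duration"),
                            holdingVoltage = -120, sampleInterval = 0.01,
                            kind = "custom") {
  sweepDimension <- match.arg(sweepDimension)
  new("VoltageProtocol",
      segments = as.data.frame(segments),
      sweptSegment = as.integer(sweptSegment),
      sweepDimension = sweepDimension,
      sweepValues = as.numeric(sweepValues),
      holdingVoltage = holdingVoltage,
      sampleInterval = sampleInterval,
      kind = kind)
}

#' @describeIn VoltageProtocol steady-state inactivation: conditioning pulses
#'   of `conditioningMs` to the voltages in `conditioningVoltages`, each
#'   followed by a test pulse.
#' @param conditioningVoltages swept conditioning voltages, mV.
#' @param conditioningMs conditioning-pulse duration, ms.
#' @param testVoltage,testMs test pulse, mV and ms.
#' @export
ssiProtocol <- function(conditioningVoltages = seq(-100, -10, by = 5),
                        conditioningMs = 50, testVoltage = -20, testMs = 10,
                        holdingVoltage = -120, sampleInterval = 0.01) {
  VoltageProtocol(
    segments = data.frame(voltage = c(NA_real_, testVoltage),
                          duration = c(conditioningMs, testMs)),
    sweptSegment = 1L, sweepValues = conditioningVoltages,
    sweepDimension = "voltage",
    holdingVoltage = holdingVoltage, sampleInterval = sampleInterval,
    kind = "ssi")
}

#' @describeIn VoltageProtocol recovery from inactivation: a depolarizing
#'   prepulse, a swept recovery interval at the holding potential, then a
#'   test pulse.
#' @param intervals swept recovery intervals, ms.
#' @param prepulseMs prepulse duration, ms (100 for recovery from fast, 1000
#'   for recovery from slow inactivated states).
#' @param prepulseVoltage prepulse potential, mV.
#' @export
recoveryProtocol <- function(intervals = 10^seq(log10(0.1), log10(1e4),
                                                length.out = 36),
                             prepulseMs = 100, prepulseVoltage = -20,
                             testVoltage = -20, testMs = 10,
                             holdingVoltage = -120, sampleInterval = 0.01) {
  VoltageProtocol(
    segments = data.frame(
      voltage = c(prepulseVoltage, holdingVoltage, testVoltage),
      duration = c(prepulseMs, NA_real_, testMs)),
    sweptSegment = 2L, sweepValues = intervals,
    sweepDimension = "duration",
    holdingVoltage = holdingVoltage, sampleInterval = sampleInterval,
    kind = "recovery")
}

#' @describeIn VoltageProtocol activation: depolarizing steps; the swept step
#'   is itself the test pulse.
#' @param stepVoltages swept step potentials, mV.
#' @param stepMs step duration, ms.
#' @export
activationProtocol <- function(stepVoltages = seq(-100, 70, by = 10),
                               stepMs = 20, holdingVoltage = -140,
                               sampleInterval = 0.01) {
  VoltageProtocol(
    segments = data.frame(voltage = NA_real_, duration = stepMs),
    sweptSegment = 1L, sweepValues = stepVoltages,
    sweepDimension = "voltage",
    holdingVoltage = holdingVoltage, sampleInterval = sampleInterval,
    kind = "activation")
}

## Realize the segment table for one sweep value.
.realizeSegments <- function(protocol, sweepValue) {
  seg <- protocol@segments
  i <- protocol@sweptSegment
  if (protocol@sweepDimension == "voltage") seg$voltage[i] <- sweepValue
  else seg$duration[i] <- sweepValue
  seg
}
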