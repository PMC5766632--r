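#' @import methods
#' @include constants.R
NULL

## ---------------------------------------------------------------------------
## VoltageProtocol
## ---------------------------------------------------------------------------

#' VoltageProtocol: a piecewise-constant voltage-clamp stimulus
#'
#' A protocol is an ordered list of (voltage, duration) segments, exactly one
#' of which is swept: either its voltage (steady-state inactivation,
#' activation) or its duration (recovery interval) takes the values in
#' `sweepValues`. The cell is assumed to rest at `holdingVoltage` before the
#' first segment, so simulations start from the stationary occupancy at the
#' holding potential.
#'
#' @slot segments data.frame with columns `voltage` (mV) and `duration` (ms).
#' @slot sweptSegment index of the swept segment.
#' @slot sweepDimension `"voltage"` or `"duration"`.
#' @slot sweepValues strictly monotone numeric vector (mV or ms).
#' @slot holdingVoltage resting potential between sweeps, mV.
#' @slot sampleInterval sampling step for simulated trajectories, ms.
#' @slot kind one of `"ssi"`, `"recovery"`, `"activation"`, `"custom"`.
#' @export
setClass("VoltageProtocol",
  representation(
    segments = "data.frame",
    sweptSegment = "integer",
    sweepDimension = "character",
    sweepValues = "numeric",
    holdingVoltage = "numeric",
    sampleInterval = "numeric",
    kind = "character"
  )
)

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  seg <- object@segments
  if (!all(c("voltage", "duration") %in% names(seg)))
    msg <- c(msg, "segments must have columns 'voltage' and 'duration'")
  else {
    fixed <- seq_len(nrow(seg))
    if (identical(object@sweepDimension, "duration"))
      fixed <- setdiff(fixed, object@sweptSegment)
    if (any(!is.finite(seg$duration[fixed])) || any(seg$duration[fixed] <= 0))
      msg <- c(msg, "all segment durations must be positive")
  }
  if (length(object@sweptSegment) != 1L ||
      object@sweptSegment < 1L || object@sweptSegment > nrow(seg))
    msg <- c(msg, "exactly one swept segment, within the segment list")
  if (!object@sweepDimension %in% c("voltage", "duration"))
    msg <- c(msg, "sweepDimension must be 'voltage' or 'duration'")
  sv <- object@sweepValues
  if (length(sv) == 0L || any(!is.finite(sv)))
    msg <- c(msg, "sweepValues must be non-empty and finite")
  else if (length(sv) > 1L && !(all(diff(sv) > 0) || all(diff(sv) < 0)))
    msg <- c(msg, "sweepValues must be strictly monotone")
  if (identical(object@sweepDimension, "duration") && any(sv <= 0))
    msg <- c(msg, "swept durations must be positive")
  if (length(object@sampleInterval) != 1L || object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be a single positive number")
  if (!object@kind %in% c("ssi", "recovery", "activation", "custom"))
    msg <- c(msg, "kind must be ssi, recovery, activation or custom")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GatingScheme
## ---------------------------------------------------------------------------

#' GatingScheme: a Markov state model with voltage-dependent rates
#'
#' Transition rates have the exponential form
#' `r(V) = amplitude * exp(sign * V / voltageSensitivity)` (ms^-1, V in mV;
#' `sign = 0` gives a voltage-independent rate). The single conducting state
#' carries a driving-force current `conductance * (V - reversalPotential)`
#' in arbitrary units. States listed in `inactivatedStates` are unavailable;
#' the subset in `slowStates` equilibrates on a much slower time scale and is
#' excluded when the fast-inactivation availability curve is evaluated.
#'
#' @slot stateLabels ordered state names.
#' @slot conductingState the open state label.
#' @slot inactivatedStates labels of non-conducting inactivated states.
#' @slot slowStates labels of slow inactivated states (subset of
#'   `inactivatedStates`).
#' @slot rates data.frame with columns `from`, `to`, `amplitude` (ms^-1),
#'   `vsens` (mV), `sign` (-1, 0, or 1).
#' @slot conductance single-channel driving amplitude, arbitrary units.
#' @slot reversalPotential mV.
#' @export
setClass("GatingScheme",
  representation(
    stateLabels = "character",
    conductingState = "character",
    inactivatedStates = "character",
    slowStates = "character",
    rates = "data.frame",
    conductance = "numeric",
    reversalPotential = "numeric"
  )
)

setValidity("GatingScheme", function(object) {
  msg <- character()
  lab <- object@stateLabels
  if (anyDuplicated(lab)) msg <- c(msg, "state labels must be unique")
  if (length(object@conductingState) != 1L ||
      !object@conductingState %in% lab)
    msg <- c(msg, "conductingState must be one of the state labels")
  if (!all(object@inactivatedStates %in% lab))
    msg <- c(msg, "inactivatedStates must be state labels")
  if (!all(object@slowStates %in% object@inactivatedStates))
    msg <- c(msg, "slowStates must be a subset of inactivatedStates")
  r <- object@rates
  need <- c("from", "to", "amplitude", "vsens", "sign")
  if (!all(need %in% names(r))) {
    msg <- c(msg, "rates needs columns from, to, amplitude, vsens, sign")
  } else {
    if (!all(r$from %in% lab) || !all(r$to %in% lab))
      msg <- c(msg, "rate endpoints must be state labels")
    if (any(!is.finite(r$amplitude)) || any(r$amplitude < 0))
      msg <- c(msg, "rate amplitudes must be finite and non-negative")
    if (any(!is.finite(r$vsens)) || any(r$vsens <= 0))
      msg <- c(msg, "voltage sensitivities must be positive")
    if (!all(r$sign %in% c(-1, 0, 1)))
      msg <- c(msg, "rate sign must be -1, 0 or 1")
  }
  if (length(object@conductance) != 1L || !is.finite(object@conductance))
    msg <- c(msg, "conductance must be a single finite number")
  if (length(object@reversalPotential) != 1L ||
      !is.finite(object@reversalPotential))
    msg <- c(msg, "reversalPotential must be a single finite number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PhenoParams
## ---------------------------------------------------------------------------

#' PhenoParams: phenomenological gating parameters of one construct
#'
#' Closed-form description of a construct's gating: Boltzmann midpoint and
#' slope of steady-state inactivation, multi-exponential recovery components
#' per prepulse class, and a conductance-voltage description of activation.
#' Blocks that a construct does not use may be left `NA` / empty.
#'
#' @slot constructId construct name.
#' @slot inactV12,inactSlope Boltzmann midpoint and slope factor, mV.
#' @slot recovery named list of data.frames (columns `amplitude`, `tau` in
#'   ms), one per prepulse class, conventionally `"p100ms"` and `"p1s"`.
#' @slot actV12,actSlope,actReversal activation midpoint, slope factor and
#'   reversal potential, mV.
#' @export
setClass("PhenoParams",
  representation(
    constructId = "character",
    inactV12 = "numeric",
    inactSlope = "numeric",
    recovery = "list",
    actV12 = "numeric",
    actSlope = "numeric",
    actReversal = "numeric"
  ),
  prototype(
    recovery = list(),
    actV12 = NA_real_, actSlope = NA_real_, actReversal = NA_real_
  )
)

setValidity("PhenoParams", function(object) {
  msg <- character()
  if (length(object@constructId) != 1L || !nzchar(object@constructId))
    msg <- c(msg, "constructId must be a single non-empty string")
  if (is.finite(object@inactSlope) && object@inactSlope <= 0)
    msg <- c(msg, "inactivation slope factor must be positive")
  if (is.finite(object@actSlope) && object@actSlope <= 0)
    msg <- c(msg, "activation slope factor must be positive")
  for (cls in names(object@recovery)) {
    comp <- object@recovery[[cls]]
    if (!all(c("amplitude", "tau") %in% names(comp))) {
      msg <- c(msg, sprintf("recovery class '%s' needs amplitude and tau", cls))
      next
    }
    if (any(comp$amplitude < 0))
      msg <- c(msg, sprintf("recovery amplitudes in '%s' must be >= 0", cls))
    if (sum(comp$amplitude) > 1 + 1e-8)
      msg <- c(msg, sprintf("recovery amplitudes in '%s' must sum to <= 1", cls))
    if (any(comp$tau <= 0))
      msg <- c(msg, sprintf("recovery time constants in '%s' must be > 0", cls))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PeakSeries
## ---------------------------------------------------------------------------

#' PeakSeries: normalized peak current versus the swept variable
#'
#' Rows of `y` are replicates; columns correspond to the swept values `x`
#' (mV for steady-state inactivation and activation, ms for recovery).
#'
#' @slot constructId construct name.
#' @slot protocolKind `"ssi"`, `"recovery"` or `"activation"`.
#' @slot x strictly monotone swept values.
#' @slot y replicate-by-x matrix of (normalized) peak currents.
#' @slot temperature recording temperature, K.
#' @export
setClass("PeakSeries",
  representation(
    constructId = "character",
    protocolKind = "character",
    x = "numeric",
    y = "matrix",
    temperature = "numeric"
  ),
  prototype(temperature = 291.15)
)

## Margin allowed outside [0, 1] for noisy normalized ssi data.
.SSI_NOISE_MARGIN <- 0.5

setValidity("PeakSeries", function(object) {
  msg <- character()
  if (!object@protocolKind %in% c("ssi", "recovery", "activation"))
    msg <- c(msg, "protocolKind must be ssi, recovery or activation")
  x <- object@x
  if (length(x) < 1L || any(!is.finite(x)))
    msg <- c(msg, "x must be non-empty and finite")
  else if (length(x) > 1L && !(all(diff(x) > 0) || all(diff(x) < 0)))
    msg <- c(msg, "x must be strictly monotone")
  if (ncol(object@y) != length(x))
    msg <- c(msg, "y must have one column per x value")
  if (nrow(object@y) < 1L)
    msg <- c(msg, "at least one replicate is required")
  if (identical(object@protocolKind, "ssi") && length(object@y) &&
      (min(object@y) < -.SSI_NOISE_MARGIN ||
       max(object@y) > 1 + .SSI_NOISE_MARGIN))
    msg <- c(msg, "normalized ssi currents fall far outside [0, 1]")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number (K)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' BoltzmannFit: steady-state inactivation fit
#'
#' Least-squares fit of `y = 1 / (1 + exp((V - V1/2) / k))` to a normalized
#' availability curve. The effective valence is derived as `z = RT / (F k)`
#' so that `z * k = RT/F` holds exactly; its standard error follows by the
#' delta method.
#'
#' @slot v12,v12SE midpoint and its standard error, mV.
#' @slot slope,slopeSE slope factor k and its standard error, mV.
#' @slot z,zSE effective valence and its standard error.
#' @slot temperature K.
#' @slot residualRMS root-mean-square residual of the fit.
#' @slot nPoints number of fitted points (per-voltage means).
#' @slot covariance 2x2 parameter covariance matrix (v12, slope).
#' @slot flags diagnostic flags, e.g. `"slope_at_bound"`.
#' @export
setClass("BoltzmannFit",
  representation(
    v12 = "numeric", v12SE = "numeric",
    slope = "numeric", slopeSE = "numeric",
    z = "numeric", zSE = "numeric",
    temperature = "numeric",
    residualRMS = "numeric", nPoints = "integer",
    covariance = "matrix", flags = "character"
  )
)

setValidity("BoltzmannFit", function(object) {
  msg <- character()
  if (object@slope <= 0) msg <- c(msg, "slope factor must be positive")
  rel <- abs(object@z * object@slope - rtfMillivolts(object@temperature)) /
    rtfMillivolts(object@temperature)
  if (rel > 1e-9) msg <- c(msg, "z must equal RT/(F k)")
  if (any(c(object@v12SE, object@slopeSE, object@zSE) < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RecoveryFit: multi-exponential fit of recovery from inactivation
#'
#' Fit of `y = C - sum_i A_i exp(-t / tau_i)` with 2 or 3 components.
#' Components are ordered by ascending time constant; equal time constants
#' are tie-broken by descending amplitude.
#'
#' @slot nComponents 2 or 3.
#' @slot amplitudes,amplitudeSE component amplitudes (fractions) and SEs.
#' @slot tau,tauSE time constants (ms, ascending) and SEs.
#' @slot offset,offsetSE final recovery level C and its SE.
#' @slot residualRMS root-mean-square residual.
#' @slot nPoints number of fitted points.
#' @slot flags diagnostic flags, e.g. `"tau_degenerate"`.
#' @export
setClass("RecoveryFit",
  representation(
    nComponents = "integer",
    amplitudes = "numeric", amplitudeSE = "numeric",
    tau = "numeric", tauSE = "numeric",
    offset = "numeric", offsetSE = "numeric",
    residualRMS = "numeric", nPoints = "integer",
    flags = "character"
  )
)

setValidity("RecoveryFit", function(object) {
  msg <- character()
  if (!object@nComponents %in% c(2L, 3L))
    msg <- c(msg, "nComponents must be 2 or 3")
  if (length(object@tau) != object@nComponents ||
      length(object@amplitudes) != object@nComponents)
    msg <- c(msg, "one amplitude and one tau per component")
  if (is.unsorted(object@tau)) msg <- c(msg, "tau must be sorted ascending")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@tau <= 0)) msg <- c(msg, "time constants must be positive")
  if (length(msg)) msg else TRUE
})

#' ActivationFit: conductance-voltage fit of peak current-voltage data
#'
#' Fit of `I = Gmax (V - Vrev) (1 - 1 / (1 + exp((V - Va1/2) / K)))`.
#'
#' @slot gMax,gMaxSE maximum conductance (arbitrary units) and SE.
#' @slot vRev,vRevSE reversal potential, mV.
#' @slot va12,va12SE activation midpoint, mV.
#' @slot slope,slopeSE slope factor K, mV.
#' @slot residualRMS root-mean-square residual.
#' @slot nPoints number of fitted points.
#' @slot flags diagnostic flags, e.g. `"vrev_extrapolated"`.
#' @export
setClass("ActivationFit",
  representation(
    gMax = "numeric", gMaxSE = "numeric",
    vRev = "numeric", vRevSE = "numeric",
    va12 = "numeric", va12SE = "numeric",
    slope = "numeric", slopeSE = "numeric",
    residualRMS = "numeric", nPoints = "integer",
    flags = "character"
  )
)

setValidity("ActivationFit", function(object) {
  if (object@slope <= 0) "slope factor K must be positive" else TRUE
})

## ---------------------------------------------------------------------------
## Energetics
## ---------------------------------------------------------------------------

#' FreeEnergy: free energy of inactivation for one construct
#'
#' `deltaG = z F V1/2` in kcal/mol, with the relative-error propagation
#' `SE = |deltaG| sqrt((SE_z/z)^2 + (SE_V12/V12)^2)`.
#'
#' @slot constructId construct name.
#' @slot deltaG kcal/mol.
#' @slot se standard error, kcal/mol.
#' @slot temperature K.
#' @slot flags diagnostic flags, e.g. `"abs_se_fallback"` when V1/2 = 0.
#' @export
setClass("FreeEnergy",
  representation(
    constructId = "character",
    deltaG = "numeric", se = "numeric",
    temperature = "numeric", flags = "character"
  )
)

setValidity("FreeEnergy", function(object) {
  msg <- character()
  if (!is.finite(object@deltaG)) msg <- c(msg, "deltaG must be finite")
  if (!is.finite(object@se) || object@se < 0)
    msg <- c(msg, "se must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' CycleResult: double-mutant-cycle coupling energy for one quartet
#'
#' `ddG = (dG_MUT1 - dG_WT) - (dG_MUT1/MUT2 - dG_MUT2)`; the quartet is
#' classified as directly coupled when `|ddG|` exceeds the threshold
#' (1 kcal/mol by convention).
#'
#' @slot ids named character vector with elements `wt`, `mut1`, `mut2`,
#'   `double`.
#' @slot deltaDeltaG coupling energy, kcal/mol.
#' @slot se standard error, kcal/mol.
#' @slot seMode `"printed"` (quadrature of the two single-mutant SEs) or
#'   `"full"` (all four constructs).
#' @slot threshold kcal/mol.
#' @slot coupled logical verdict, `|ddG| > threshold`.
#' @export
setClass("CycleResult",
  representation(
    ids = "character",
    deltaDeltaG = "numeric", se = "numeric",
    seMode = "character",
    threshold = "numeric", coupled = "logical"
  )
)

setValidity("CycleResult", function(object) {
  msg <- character()
  if (!all(c("wt", "mut1", "mut2", "double") %in% names(object@ids)))
    msg <- c(msg, "ids must name wt, mut1, mut2 and double")
  if (!identical(object@coupled,
                 abs(object@deltaDeltaG) > object@threshold))
    msg <- c(msg, "coupled must equal |ddG| > threshold")
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: Pearson correlation of paired gating shifts
#'
#' @slot r Pearson correlation coefficient.
#' @slot p two-tailed p-value.
#' @slot nUsed pairs used after exclusion.
#' @slot excluded construct ids excluded, with reasons as names.
#' @slot slope,intercept least-squares regression line of y on x.
#' @export
setClass("CorrelationResult",
  representation(
    r = "numeric", p = "numeric", nUsed = "integer",
    excluded = "character",
    slope = "numeric", intercept = "numeric"
  )
)

setValidity("CorrelationResult", function(object) {
  if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
    "|r| must be <= 1" else TRUE
})
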