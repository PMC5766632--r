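#' @include AllClasses.R
NULL

#' Construct phenomenological gating parameters
#'
#' @param constructId construct name.
#' @param inactV12,inactSlope steady-state inactivation Boltzmann midpoint
#'   and slope factor, mV.
#' @param recovery named list of data.frames with columns `amplitude` and
#'   `tau` (ms); conventional class names are `"p100ms"` (up to three
#'   components) and `"p1s"` (two components).
#' @param actV12,actSlope,actReversal activation parameters, mV.
#' @return a [PhenoParams-class] object.
#' @export
PhenoParams <- function(constructId, inactV12 = NA_real_,
                        inactSlope = NA_real_, recovery = list(),
                        actV12 = NA_real_, actSlope = NA_real_,
                        actReversal = NA_real_) {
  new("PhenoParams", constructId = constructId,
      inactV12 = as.numeric(inactV12), inactSlope = as.numeric(inactSlope),
      recovery = recovery,
      actV12 = as.numeric(actV12), actSlope = as.numeric(actSlope),
      actReversal = as.numeric(actReversal))
}

#' Generate a noiseless peak series from closed-form gating parameters
#'
#' Inverts the fitted forms used for analysis:
#' steady-state inactivation `y = 1 / (1 + exp((V - V1/2) / k))` (so
#' hyperpolarized prepulses give y near 1), recovery
#' `y = 1 - sum_i A_i exp(-t / tau_i)`, and the activation current-voltage
#' relation `I = (V - Vrev) (1 - 1 / (1 + exp((V - Va1/2) / K)))` with unit
#' maximum conductance.
#'
#' @param params a [PhenoParams-class].
#' @param protocolKind `"ssi"`, `"recovery"` or `"activation"`.
#' @param x swept values: conditioning voltage (mV), recovery interval (ms)
#'   or step potential (mV).
#' @param recoveryClass which recovery component set to use (name into
#'   `params@recovery`), default `"p100ms"`.
#' @param temperature K.
#' @return a single-replicate [PeakSeries-class].
#' @export
genPhenoSeries <- function(params,
                           protocolKind = c("ssi", "recovery", "activation"),
                           x, recoveryClass = "p100ms",
                           temperature = 291.15) {
  validObject(params)
  protocolKind <- match.arg(protocolKind)
  x <- as.numeric(x)
  y <- switch(protocolKind,
    ssi = {
      if (!is.finite(params@inactSlope) || params@inactSlope <= 0)
        stop("inactivation slope factor must be positive")
      1 / (1 + exp((x - params@inactV12) / params@inactSlope))
    },
    recovery = {
      comp <- params@recovery[[recoveryClass]]
      if (is.null(comp))
        stop(sprintf("construct '%s' has no recovery class '%s'",
                     params@constructId, recoveryClass))
      if (any(comp$tau <= 0)) stop("recovery time constants must be positive")
      1 - colSums(comp$amplitude *
                    exp(-outer(comp$tau, x, function(tau, t) t / tau)))
    },
    activation = {
      if (!is.finite(params@actSlope) || params@actSlope <= 0)
        stop("activation slope factor must be positive")
      (x - params@actReversal) *
        (1 - 1 / (1 + exp((x - params@actV12) / params@actSlope)))
    })
  new("PeakSeries",
      constructId = params@constructId, protocolKind = protocolKind,
      x = x, y = matrix(y, nrow = 1), temperature = temperature)
}
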