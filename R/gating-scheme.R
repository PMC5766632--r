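#' @include AllClasses.R
NULL

#' Construct a Markov gating scheme
#'
#' @param stateLabels ordered state names.
#' @param conductingState the open state.
#' @param rates data.frame with columns `from`, `to`, `amplitude` (ms^-1),
#'   `vsens` (mV) and `sign` in `{-1, 0, 1}`; each row defines
#'   `r(V) = amplitude * exp(sign * V / vsens)`.
#' @param inactivatedStates non-conducting unavailable states.
#' @param slowStates slow inactivated states (subset of
#'   `inactivatedStates`), excluded from the fast availability curve.
#' @param conductance single-channel driving amplitude (arbitrary units).
#' @param reversalPotential mV.
#' @return a [GatingScheme-class] object.
#' @export
GatingScheme <- function(stateLabels, conductingState, rates,
                         inactivatedStates = character(),
                         slowStates = character(),
                         conductance = 1, reversalPotential = 60) {
  new("GatingScheme",
      stateLabels = stateLabels, conductingState = conductingState,
      inactivatedStates = inactivatedStates, slowStates = slowStates,
      rates = as.data.frame(rates),
      conductance = conductance, reversalPotential = reversalPotential)
}

#' Default five-state sodium-channel gating scheme
#'
#' A linear chain C1 - C2 - O - If - Is: two closed states, the open state,
#' a fast and a slow inactivated state. The activation steps (C1-C2-O) are
#' fast and complete at conditioning voltages, so the steady-state
#' availability curve is governed by the O-If equilibrium; its amplitudes
#' and voltage sensitivities are chosen so that the designed fast
#' availability curve is a Boltzmann with the requested midpoint and slope
#' factor. The If-Is step equilibrates over hundreds of milliseconds and
#' supplies the slow component of recovery.
#'
#' @param midpoint designed availability midpoint, mV.
#' @param slope designed availability slope factor, mV.
#' @return a [GatingScheme-class] object.
#' @export
defaultGatingScheme <- function(midpoint = -43.7, slope = 10.1) {
  stopifnot(slope > 0, slope < 30)
  sIO <- 30                           # recovery-rate voltage sensitivity, mV
  sOI <- 1 / (1 / slope - 1 / sIO)    # onset sensitivity completing 1/k
  b <- 0.00916                        # If -> O amplitude, ms^-1
  a <- b * exp(-midpoint / slope)     # O -> If amplitude, ms^-1
  rates <- data.frame(
    from = c("C1", "C2", "C2", "O", "O",  "If", "If", "Is"),
    to   = c("C2", "C1", "O",  "C2", "If", "O",  "Is", "If"),
    amplitude = c(400, 400 / exp(12), 150, 150 / exp(12), a, b, 0.006, 0.002),
    vsens = c(15, 15, 15, 15, sOI, sIO, 100, 80),
    sign = c(1, -1, 1, -1, 1, -1, 1, -1)
  )
  GatingScheme(
    stateLabels = c("C1", "C2", "O", "If", "Is"),
    conductingState = "O",
    rates = rates,
    inactivatedStates = c("If", "Is"),
    slowStates = "Is",
    conductance = 1, reversalPotential = 60)
}

#' Rate-generator matrix of a gating scheme at a fixed voltage
#'
#' Builds the master-equation generator Q (rows index the source state; row
#' sums are zero) at voltage `voltage`. Occupancy evolves as `dp/dt = p Q`.
#'
#' @param scheme a [GatingScheme-class].
#' @param voltage membrane potential, mV.
#' @return a square numeric matrix, states in `scheme@stateLabels` order.
#' @export
rateMatrix <- function(scheme, voltage) {
  lab <- scheme@stateLabels
  n <- length(lab)
  Q <- matrix(0, n, n, dimnames = list(lab, lab))
  r <- scheme@rates
  val <- r$amplitude * exp(r$sign * voltage / r$vsens)
  bad <- !is.finite(val) | val < 0
  if (any(bad)) {
    stop(sprintf("non-finite or negative rate for transition(s) %s at %g mV",
                 paste(sprintf("%s->%s", r$from[bad], r$to[bad]),
                       collapse = ", "),
                 voltage))
  }
  for (i in seq_len(nrow(r))) Q[r$from[i], r$to[i]] <- Q[r$from[i], r$to[i]] + val[i]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Stationary occupancy at a fixed voltage
#'
#' Null-space solution of the master equation, normalized to sum to one.
#'
#' @inheritParams rateMatrix
#' @return named probability vector over states.
#' @export
stationaryOccupancy <- function(scheme, voltage) {
  Q <- rateMatrix(scheme, voltage)
  ## p Q = 0, sum(p) = 1  ->  solve the augmented least-squares system
  A <- rbind(t(Q), rep(1, ncol(Q)))
  b <- c(rep(0, ncol(Q)), 1)
  p <- qr.solve(A, b)
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- scheme@stateLabels
  p
}

#' Fast steady-state availability of a gating scheme
#'
#' Stationary probability of not being inactivated, computed on the scheme
#' with the slow states removed (the fast subsystem). This is the
#' availability a 50 ms conditioning pulse probes: long enough for the fast
#' inactivation equilibrium, short enough that slow states stay empty.
#'
#' @inheritParams rateMatrix
#' @return availability in `[0, 1]` (vectorized over `voltage`).
#' @export
fastAvailability <- function(scheme, voltage) {
  fast <- setdiff(scheme@stateLabels, scheme@slowStates)
  avail <- setdiff(fast, scheme@inactivatedStates)
  vapply(voltage, function(V) {
    Q <- rateMatrix(scheme, V)[fast, fast, drop = FALSE]
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)              # re-close within the subsystem
    A <- rbind(t(Q), rep(1, length(fast)))
    p <- qr.solve(A, c(rep(0, length(fast)), 1))
    sum(pmax(p[match(avail, fast)], 0)) / sum(pmax(p, 0))
  }, numeric(1))
}

#' Designed availability midpoint of a gating scheme
#'
#' Voltage at which the fast steady-state availability equals one half,
#' found by root bracketing on the closed-form stationary distribution.
#' This is the design quantity a simulated steady-state inactivation curve
#' should reproduce after the generate-and-fit round trip.
#'
#' @param scheme a [GatingScheme-class].
#' @param interval search interval, mV.
#' @return midpoint voltage, mV.
#' @export
designedMidpoint <- function(scheme, interval = c(-140, 70)) {
  f <- function(V) fastAvailability(scheme, V) - 0.5
  stats::uniroot(f, interval, tol = 1e-10)$root
}
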