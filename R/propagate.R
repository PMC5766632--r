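#' @include gating-scheme.R protocols.R
NULL

## Matrix exponential propagator for one segment, dense matrix.
.expmStep <- function(Q, dt) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
}

## Occupancy at the end of a segment (single exact step).
.propagateEnd <- function(p, Q, duration) {
  as.numeric(p %*% .expmStep(Q, duration))
}

## Dense occupancy trajectory through one segment. Returns a matrix with one
## row per sample time (sampleInterval grid, plus the segment end point).
.propagateDense <- function(p, Q, duration, dt) {
  nFull <- floor(duration / dt + 1e-9)
  times <- seq_len(nFull) * dt
  rem <- duration - nFull * dt
  Tstep <- .expmStep(Q, dt)
  occ <- matrix(NA_real_, nFull + (rem > 1e-12), length(p))
  cur <- p
  for (i in seq_len(nFull)) {
    cur <- as.numeric(cur %*% Tstep)
    occ[i, ] <- cur
  }
  if (rem > 1e-12) {
    cur <- .propagateEnd(cur, Q, rem)
    occ[nFull + 1L, ] <- cur
    times <- c(times, duration)
  }
  list(times = times, occupancy = occ, final = cur)
}

#' Propagate a gating scheme through a voltage protocol
#'
#' Integrates the master equation `dp/dt = p Q(V)` through every sweep of a
#' piecewise-constant protocol. Because the voltage is constant within a
#' segment, each segment is propagated exactly by the matrix exponential of
#' its rate generator; no integrator tolerance enters. The initial occupancy
#' defaults to the stationary distribution at the holding potential.
#'
#' @param scheme a [GatingScheme-class].
#' @param protocol a [VoltageProtocol-class].
#' @param initialOccupancy probability vector over states (sums to one);
#'   default: stationary occupancy at the holding potential.
#' @return a list with one element per sweep value, each a list with
#'   `sweepValue`, `time` (ms from sweep start), `voltage` (per sample) and
#'   `occupancy` (samples-by-states matrix). Occupancy rows sum to one
#'   within 1e-9.
#' @export
propagateScheme <- function(scheme, protocol, initialOccupancy = NULL) {
  validObject(scheme); validObject(protocol)
  n <- length(scheme@stateLabels)
  if (is.null(initialOccupancy)) {
    initialOccupancy <- stationaryOccupancy(scheme, protocol@holdingVoltage)
  }
  stopifnot(length(initialOccupancy) == n)
  if (abs(sum(initialOccupancy) - 1) > 1e-9)
    stop("initialOccupancy must sum to 1")
  dt <- protocol@sampleInterval
  lapply(protocol@sweepValues, function(sv) {
    seg <- .realizeSegments(protocol, sv)
    p <- as.numeric(initialOccupancy)
    times <- numeric(); volts <- numeric()
    occ <- matrix(numeric(), 0, n)
    t0 <- 0
    for (i in seq_len(nrow(seg))) {
      Q <- rateMatrix(scheme, seg$voltage[i])
      res <- .propagateDense(p, Q, seg$duration[i], dt)
      times <- c(times, t0 + res$times)
      volts <- c(volts, rep(seg$voltage[i], length(res$times)))
      occ <- rbind(occ, res$occupancy)
      p <- res$final
      t0 <- t0 + seg$duration[i]
    }
    sums <- rowSums(occ)
    if (any(abs(sums - 1) > 1e-9))
      stop("occupancy conservation violated beyond 1e-9")
    colnames(occ) <- scheme@stateLabels
    list(sweepValue = sv, time = times, voltage = volts, occupancy = occ)
  })
}

#' Fine-step Runge-Kutta reference integrator
#'
#' Classical fourth-order Runge-Kutta integration of the master equation at
#' a fixed fine step, used as an independent cross-check of the
#' matrix-exponential propagator. Returns occupancies on the same sample
#' grid as [propagateScheme()] for a single sweep value.
#'
#' @inheritParams propagateScheme
#' @param sweepValue the single sweep value to integrate.
#' @param step integrator step, ms.
#' @return list with `time` and `occupancy` as in [propagateScheme()].
#' @export
integrateSchemeRK4 <- function(scheme, protocol, sweepValue,
                               initialOccupancy = NULL, step = 1e-3) {
  validObject(scheme); validObject(protocol)
  if (is.null(initialOccupancy))
    initialOccupancy <- stationaryOccupancy(scheme, protocol@holdingVoltage)
  seg <- .realizeSegments(protocol, sweepValue)
  dt <- protocol@sampleInterval
  p <- as.numeric(initialOccupancy)
  times <- numeric()
  occ <- matrix(numeric(), 0, length(p))
  t0 <- 0
  for (i in seq_len(nrow(seg))) {
    Q <- rateMatrix(scheme, seg$voltage[i])
    dur <- seg$duration[i]
    nOut <- floor(dur / dt + 1e-9)
    outTimes <- seq_len(nOut) * dt
    if (dur - nOut * dt > 1e-12) outTimes <- c(outTimes, dur)
    segOcc <- matrix(NA_real_, length(outTimes), length(p))
    tcur <- 0
    for (j in seq_along(outTimes)) {
      target <- outTimes[j]
      while (tcur < target - 1e-12) {
        h <- min(step, target - tcur)
        k1 <- as.numeric(p %*% Q)
        k2 <- as.numeric((p + h / 2 * k1) %*% Q)
        k3 <- as.numeric((p + h / 2 * k2) %*% Q)
        k4 <- as.numeric((p + h * k3) %*% Q)
        p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        tcur <- tcur + h
      }
      segOcc[j, ] <- p
    }
    times <- c(times, t0 + outTimes)
    occ <- rbind(occ, segOcc)
    t0 <- t0 + dur
  }
  colnames(occ) <- scheme@stateLabels
  list(time = times, occupancy = occ)
}
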