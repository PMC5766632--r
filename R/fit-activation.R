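#' @include fit-boltzmann.R
NULL

#' Fit a conductance-voltage relation to peak current-voltage data
#'
#' Least-squares fit of
#' `I = Gmax (V - Vrev) (1 - 1 / (1 + exp((V - Va1/2) / K)))`
#' to peak currents versus step potential. A reversal potential estimated
#' outside the sampled voltage range is flagged `"vrev_extrapolated"`.
#'
#' @param series an activation [PeakSeries-class] (peak current, signed,
#'   versus step potential).
#' @return an [ActivationFit-class].
#' @export
fitActivation <- function(series) {
  d <- .meansFrame(series)
  if (nrow(d) < 6L) stop("need at least 6 step potentials")
  ## starting values: reversal near the depolarized zero crossing,
  ## midpoint near half-maximal current magnitude
  iPk <- which.max(abs(d$y))
  vrev0 <- {
    above <- d$x > d$x[iPk]
    zc <- which(above & abs(d$y) < 0.1 * abs(d$y[iPk]))
    if (length(zc)) d$x[zc[1]] else max(d$x) + 10
  }
  va0 <- d$x[which.min(abs(abs(d$y) - abs(d$y[iPk]) / 2))]
  g0 <- d$y[iPk] / (d$x[iPk] - vrev0)
  start <- list(gMax = g0, vRev = vrev0, va12 = va0, k = 7)
  lower <- c(gMax = -Inf, vRev = min(d$x) - 200, va12 = min(d$x) - 100,
             k = .SLOPE_BOUNDS[1])
  upper <- c(gMax = Inf, vRev = max(d$x) + 200, va12 = max(d$x) + 100,
             k = .SLOPE_BOUNDS[2])
  fit <- .fitWithRestarts(
    y ~ gMax * (x - vRev) * (1 - 1 / (1 + exp((x - va12) / k))),
    d, start, lower, upper)
  if (is.null(fit))
    stop("activation fit did not converge after ", .MAX_RESTARTS, " restarts")
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  flags <- character()
  if (est[["vRev"]] < min(d$x) || est[["vRev"]] > max(d$x))
    flags <- c(flags, "vrev_extrapolated")
  new("ActivationFit",
      gMax = est[["gMax"]], gMaxSE = se[["gMax"]],
      vRev = est[["vRev"]], vRevSE = se[["vRev"]],
      va12 = est[["va12"]], va12SE = se[["va12"]],
      slope = est[["k"]], slopeSE = se[["k"]],
      residualRMS = sqrt(mean(stats::resid(fit)^2)),
      nPoints = nrow(d), flags = flags)
}
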