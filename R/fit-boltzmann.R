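#' @include AllClasses.R noise.R
NULL

## Slope-factor bounds shared by the Boltzmann and activation fits, mV.
.SLOPE_BOUNDS <- c(0.1, 100)
.RESTART_SEED <- 101L
.MAX_RESTARTS <- 20L

## Run nlsLM with jittered multi-starts under a fixed local RNG; returns the
## converged fit with the smallest residual sum of squares, or NULL.
.fitWithRestarts <- function(formula, data, start, lower, upper,
                             restarts = .MAX_RESTARTS) {
  tryFit <- function(st) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = st, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-10))), silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
  }
  best <- tryFit(start)
  bestSS <- if (is.null(best)) Inf else sum(stats::resid(best)^2)
  if (is.finite(bestSS) && bestSS < 1e-16) return(best)
  .withSeed(.RESTART_SEED, {
    for (i in seq_len(restarts)) {
      jit <- lapply(start, function(v)
        v * exp(stats::rnorm(1, sd = 0.3)) +
          stats::rnorm(1, sd = 0.05 * max(abs(v), 1e-3)))
      jit <- Map(function(v, lo, hi) pmin(pmax(v, lo), hi),
                 jit, as.list(lower), as.list(upper))
      fit <- tryFit(jit)
      if (!is.null(fit)) {
        ss <- sum(stats::resid(fit)^2)
        if (ss < bestSS * (1 - 1e-10)) { best <- fit; bestSS <- ss }
        if (bestSS < 1e-16) break
      }
    }
  })
  best
}

## Collapse a PeakSeries to per-point replicate means.
.meansFrame <- function(series) {
  data.frame(x = xValues(series), y = seriesMeans(series))
}

#' Fit a Boltzmann function to a steady-state inactivation series
#'
#' Least-squares fit of `y = 1 / (1 + exp((V - V1/2) / k))` to the
#' per-voltage replicate means of a normalized availability series. The
#' effective valence is derived from the slope factor as `z = RT / (F k)`;
#' its standard error follows by the delta method, so `z k = RT/F` holds
#' exactly for every fit.
#'
#' @param series an ssi [PeakSeries-class] (or any object with strictly
#'   monotone voltages and normalized currents).
#' @param temperature absolute temperature, K; defaults to the series
#'   temperature. Required to convert the mV slope factor into a valence.
#' @return a [BoltzmannFit-class].
#' @export
fitBoltzmann <- function(series, temperature = temperatureK(series)) {
  d <- .meansFrame(series)
  if (length(unique(d$x)) < 5L)
    stop("need at least 5 distinct voltages")
  if (diff(range(d$y)) < 0.2)
    stop("series does not span the inactivation transition; ",
         "midpoint is not identifiable")
  v0 <- d$x[which.min(abs(d$y - 0.5))]
  start <- list(v12 = v0, k = 8)
  lower <- c(v12 = min(d$x) - 100, k = .SLOPE_BOUNDS[1])
  upper <- c(v12 = max(d$x) + 100, k = .SLOPE_BOUNDS[2])
  fit <- .fitWithRestarts(y ~ 1 / (1 + exp((x - v12) / k)), d, start,
                          lower, upper)
  if (is.null(fit))
    stop("Boltzmann fit did not converge after ", .MAX_RESTARTS,
         " restarts (n = ", nrow(d), ", y range ",
         paste(signif(range(d$y), 3), collapse = ".."), ")")
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  flags <- character()
  if (est["k"] <= .SLOPE_BOUNDS[1] * 1.001 ||
      est["k"] >= .SLOPE_BOUNDS[2] * 0.999)
    flags <- c(flags, "slope_at_bound")
  rtf <- rtfMillivolts(temperature)
  z <- rtf / est[["k"]]
  zSE <- z * se[["k"]] / est[["k"]]
  new("BoltzmannFit",
      v12 = est[["v12"]], v12SE = se[["v12"]],
      slope = est[["k"]], slopeSE = se[["k"]],
      z = z, zSE = zSE, temperature = temperature,
      residualRMS = sqrt(mean(stats::resid(fit)^2)),
      nPoints = nrow(d), covariance = stats::vcov(fit), flags = flags)
}

#' Summarize Boltzmann fits of a construct library as a table
#'
#' @param fits named list of [BoltzmannFit-class] objects (names are
#'   construct ids).
#' @param n optional group sizes (replicate counts) carried into the table
#'   for the screen statistics; recycled.
#' @return data.frame with columns `constructId`, `v12`, `v12SE`, `slope`,
#'   `slopeSE`, `z`, `zSE`, `residualRMS`, `n`, `temperature`.
#' @export
fitTable <- function(fits, n = NA_integer_) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  n <- rep_len(as.integer(n), length(fits))
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(constructId = names(fits)[i],
               v12 = f@v12, v12SE = f@v12SE,
               slope = f@slope, slopeSE = f@slopeSE,
               z = f@z, zSE = f@zSE,
               residualRMS = f@residualRMS,
               n = n[i], temperature = f@temperature)
  }))
}
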