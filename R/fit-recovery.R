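#' @include fit-boltzmann.R
NULL

.TAU_BOUNDS <- c(1e-3, 1e6)

#' Fit a multi-exponential recovery time course
#'
#' Least-squares fit of `y = C - sum_i A_i exp(-t / tau_i)` with two or
#' three components to the per-interval replicate means. Amplitudes are
#' bounded below by zero and time constants to `[1e-3, 1e6]` ms.
#' Initialization is multi-start: time-constant guesses are log-spaced
#' across the sampled interval range and jittered over up to 20 restarts
#' under a fixed restart seed. Components are reported in ascending-tau
#' order (ties broken by descending amplitude); adjacent time constants
#' closer than a factor of 3 are flagged `"tau_degenerate"`.
#'
#' @param series a recovery [PeakSeries-class] with strictly increasing
#'   intervals.
#' @param nComponents 2 or 3.
#' @return a [RecoveryFit-class].
#' @export
fitRecovery <- function(series, nComponents = 3L) {
  nComponents <- as.integer(nComponents)
  stopifnot(nComponents %in% c(2L, 3L))
  d <- .meansFrame(series)
  if (any(diff(d$x) <= 0)) stop("recovery intervals must be strictly increasing")
  decades <- log10(max(d$x) / min(d$x))
  if (nComponents == 3L && decades < 3)
    stop("three-component fits need intervals spanning at least 3 decades")
  if (nrow(d) < 2 * nComponents + 2)
    stop("too few intervals for a ", nComponents, "-component fit")
  k <- nComponents
  tau0 <- 10^seq(log10(min(d$x)), log10(max(d$x)), length.out = k + 2)[2:(k + 1)]
  amp0 <- rep(max(1e-3, (max(d$y) - min(d$y)) / k), k)
  start <- c(stats::setNames(as.list(amp0), paste0("A", 1:k)),
             stats::setNames(as.list(tau0), paste0("tau", 1:k)),
             list(C = max(d$y)))
  lower <- c(rep(0, k), rep(.TAU_BOUNDS[1], k), -0.5)
  upper <- c(rep(1.5, k), rep(.TAU_BOUNDS[2], k), 1.5)
  names(lower) <- names(upper) <- names(start)
  rhs <- paste0("C - ", paste(sprintf("A%d * exp(-x / tau%d)", 1:k, 1:k),
                              collapse = " - "))
  fit <- .fitWithRestarts(stats::as.formula(paste("y ~", rhs)), d, start,
                          lower, upper)
  if (is.null(fit))
    stop("recovery fit (", k, " components) did not converge after ",
         .MAX_RESTARTS, " restarts")
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  A <- est[paste0("A", 1:k)]; tau <- est[paste0("tau", 1:k)]
  Ase <- se[paste0("A", 1:k)]; tauSE <- se[paste0("tau", 1:k)]
  ## unique component identity: ascending tau, larger amplitude first on ties
  ord <- order(tau, -A)
  A <- A[ord]; tau <- tau[ord]; Ase <- Ase[ord]; tauSE <- tauSE[ord]
  flags <- character()
  if (any(tau[-1] / tau[-k] < 3)) flags <- c(flags, "tau_degenerate")
  if (any(A < 1e-4)) flags <- c(flags, "amplitude_collapsed")
  new("RecoveryFit",
      nComponents = k,
      amplitudes = unname(A), amplitudeSE = unname(Ase),
      tau = unname(tau), tauSE = unname(tauSE),
      offset = est[["C"]], offsetSE = se[["C"]],
      residualRMS = sqrt(mean(stats::resid(fit)^2)),
      nPoints = nrow(d), flags = flags)
}
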