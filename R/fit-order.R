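#' @include fit-recovery.R
NULL

#' Choose the number of recovery components
#'
#' By convention, recovery after a 100 ms prepulse is fit with three
#' exponentials (fast plus two slow components) and recovery after a 1 s
#' prepulse with two (slow states only); with `auto = TRUE` the order is
#' instead selected by an extra-sum-of-squares F-test between the
#' two- and three-component fits at level `alpha`.
#'
#' @param series a recovery [PeakSeries-class].
#' @param prepulseClass `"p100ms"` or `"p1s"`; fixes the order unless
#'   `auto = TRUE`.
#' @param auto use the F-test instead of the prepulse-class convention.
#' @param alpha test level for `auto` mode.
#' @return a list with `order` (2 or 3), the selected `fit`, and in auto
#'   mode `fit2`, `fit3`, `fstat` and `p`.
#' @export
chooseRecoveryOrder <- function(series, prepulseClass = c("p100ms", "p1s"),
                                auto = FALSE, alpha = 0.05) {
  prepulseClass <- match.arg(prepulseClass)
  if (!auto) {
    order <- if (prepulseClass == "p100ms") 3L else 2L
    return(list(order = order, fit = fitRecovery(series, order)))
  }
  fit2 <- fitRecovery(series, 2L)
  fit3 <- fitRecovery(series, 3L)
  n <- fit3@nPoints
  p2 <- 5L; p3 <- 7L                    # parameters incl. offset
  ss2 <- fit2@residualRMS^2 * n
  ss3 <- fit3@residualRMS^2 * n
  fstat <- ((ss2 - ss3) / (p3 - p2)) / (ss3 / (n - p3))
  p <- stats::pf(fstat, p3 - p2, n - p3, lower.tail = FALSE)
  order <- if (is.finite(p) && p < alpha) 3L else 2L
  list(order = order, fit = if (order == 3L) fit3 else fit2,
       fit2 = fit2, fit3 = fit3, fstat = fstat, p = p)
}
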