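#' @include pheno.R noise.R
NULL

#' Shipped construct-parameter scenarios
#'
#' Parameter tables for the construct libraries the package ships. Each row
#' describes one construct's steady-state inactivation Boltzmann parameters
#' (midpoint and slope factor, mV, with the reported standard errors and
#' group sizes carried along for the screen statistics) plus a role column:
#' exactly one `reference` (wild type), optionally one `background` (the
#' selectivity-filter charge mutant), `mutant` for single DIV-S6 mutants and
#' `double` for background-combined constructs.
#'
#' Available scenarios:
#' \describe{
#'   \item{`oocyte-quartet`}{wild type, I1575C, K1237E and the double mutant
#'     recorded in oocytes at 18 degrees C (holding -120 mV): the canonical
#'     double-mutant-cycle quartet.}
#'   \item{`mammalian-isoform`}{wild type and the isoform-mimicking I1581V
#'     recorded in mammalian cells (holding -140 mV). Slope factors are not
#'     part of the reported parameter set; a representative 7 mV
#'     patch-clamp slope is used.}
#'   \item{`oocyte-ph`}{wild type and I1581H across bath pH 6.6 / 7.4 / 8.2,
#'     one construct per (channel, pH) pair; reference is wild type at
#'     pH 7.4. Slope factors as above (10.1 mV oocyte default).}
#' }
#'
#' @param scenario scenario name.
#' @return data.frame with columns `constructId`, `v12`, `v12SE`, `slope`,
#'   `slopeSE`, `n`, `role`, `temperature`.
#' @export
constructScenario <- function(scenario = c("oocyte-quartet",
                                           "mammalian-isoform",
                                           "oocyte-ph")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    "oocyte-quartet" = data.frame(
      constructId = c("wt", "I1575C", "K1237E", "K1237E/I1575C"),
      v12 = c(-43.7, -51.8, -51.1, -59.6),
      v12SE = c(0.5, 1.1, 1.2, 1.4),
      slope = c(10.1, 11.5, 10.8, 11.3),
      slopeSE = c(0.3, 0.3, 0.5, 0.4),
      n = c(8L, 7L, 5L, 5L),
      role = c("reference", "mutant", "background", "double"),
      temperature = 291.15),
    "mammalian-isoform" = data.frame(
      constructId = c("wt", "I1581V"),
      v12 = c(-66.2, -53.8),
      v12SE = c(0.6, 0.6),
      slope = c(7, 7),
      slopeSE = c(0.3, 0.3),
      n = c(9L, 5L),
      role = c("reference", "mutant"),
      temperature = 295.15),
    "oocyte-ph" = data.frame(
      constructId = c("wt_pH6.6", "wt_pH7.4", "wt_pH8.2",
                      "I1581H_pH6.6", "I1581H_pH7.4", "I1581H_pH8.2"),
      v12 = c(-66.5, -71.1, -69.1, -66.4, -65.8, -75.3),
      v12SE = c(1.2, 2.5, 1.0, 1.7, 1.5, 1.3),
      slope = rep(10.1, 6),
      slopeSE = rep(0.3, 6),
      n = c(8L, 8L, 8L, 5L, 5L, 5L),
      role = c("mutant", "reference", "mutant", "mutant", "mutant", "mutant"),
      temperature = 291.15))
}

#' Shipped recovery-component parameter sets
#'
#' Multi-exponential recovery parameters for wild type and the
#' selectivity-filter mutant K1237E: three components after a 100 ms
#' depolarizing prepulse (recovery from fast plus slow inactivated states)
#' and two components after a 1 s prepulse (slow states only).
#'
#' @return data.frame with columns `constructId`, `class` (`"p100ms"` or
#'   `"p1s"`), `component`, `amplitude`, `amplitudeSE`, `tau`, `tauSE` (ms),
#'   `n`.
#' @export
recoveryScenario <- function() {
  rbind(
    data.frame(constructId = "wt", class = "p100ms", component = 1:3,
               amplitude = c(0.50, 0.25, 0.25),
               amplitudeSE = c(0.02, 0.06, 0.06),
               tau = c(0.8, 231.8, 1667.8),
               tauSE = c(0.05, 62.2, 512.2), n = 3L),
    data.frame(constructId = "K1237E", class = "p100ms", component = 1:3,
               amplitude = c(0.33, 0.11, 0.56),
               amplitudeSE = c(0.03, 0.03, 0.01),
               tau = c(8.3, 295.8, 3443.8),
               tauSE = c(1.4, 100.4, 114.7), n = 3L),
    data.frame(constructId = "wt", class = "p1s", component = 1:2,
               amplitude = c(0.70, 0.30), amplitudeSE = c(0.05, 0.05),
               tau = c(486.5, 2588.1), tauSE = c(41.9, 403.9), n = 6L),
    data.frame(constructId = "K1237E", class = "p1s", component = 1:2,
               amplitude = c(0.45, 0.55), amplitudeSE = c(0.05, 0.05),
               tau = c(1804.1, 8140.6), tauSE = c(181.6, 566.7), n = 6L))
}

#' Recovery parameter sets as PhenoParams
#'
#' @param constructId `"wt"` or `"K1237E"`.
#' @return a [PhenoParams-class] carrying both recovery classes and the
#'   construct's inactivation parameters from the oocyte quartet scenario.
#' @export
recoveryPhenoParams <- function(constructId = c("wt", "K1237E")) {
  constructId <- match.arg(constructId)
  rec <- recoveryScenario()
  rec <- rec[rec$constructId == constructId, ]
  ssi <- constructScenario("oocyte-quartet")
  ssi <- ssi[ssi$constructId == constructId, ]
  PhenoParams(
    constructId = constructId,
    inactV12 = ssi$v12, inactSlope = ssi$slope,
    recovery = lapply(split(rec, rec$class), function(d)
      data.frame(amplitude = d$amplitude, tau = d$tau)))
}

#' Synthetic cysteine-scanning screen scenario
#'
#' Builds a construct table emulating a serial cysteine scan of DIV-S6
#' examined in two backgrounds (wild type and the selectivity-filter mutant
#' K1237E). Per-position midpoint shifts in the wild-type background are
#' drawn from a Gaussian spread; shifts in the mutant background are
#' constructed to have exactly the requested empirical correlation with
#' them. Optionally one antagonistic outlier position is appended (large
#' depolarizing shift in one background, large hyperpolarizing shift in the
#' other), mimicking a background-sensitive site.
#'
#' This scenario is synthetic: the per-position shift values are generated,
#' not measured, and only their correlation structure is controlled.
#'
#' @param nPositions number of scanned positions (excluding the outlier).
#' @param targetR empirical Pearson correlation between the two backgrounds'
#'   shifts.
#' @param shiftSD spread of the wild-type-background shifts, mV.
#' @param seed integer seed.
#' @param outlier append the antagonistic outlier position?
#' @param outlierShift c(wild-type-background, mutant-background) shifts of
#'   the outlier, mV.
#' @return a construct table as in [constructScenario()], with mutants named
#'   `posNN` and doubles `K1237E/posNN`.
#' @export
screenScenario <- function(nPositions = 14, targetR = 0.94, shiftSD = 6,
                           seed = 1L, outlier = FALSE,
                           outlierShift = c(20.3, -20.7)) {
  stopifnot(nPositions >= 3, abs(targetR) <= 1)
  base <- constructScenario("oocyte-quartet")
  wt <- base[base$constructId == "wt", ]
  bg <- base[base$constructId == "K1237E", ]
  sh <- .withSeed(seed, {
    x <- stats::rnorm(nPositions, 0, shiftSD)
    e <- stats::rnorm(nPositions)
    list(x = x, e = e)
  })
  x <- sh$x
  ## impose the empirical correlation exactly: orthogonalize, standardize,
  ## then mix
  xs <- scale(x)[, 1]
  e <- stats::residuals(stats::lm(sh$e ~ xs))
  es <- scale(e)[, 1]
  y <- (targetR * xs + sqrt(1 - targetR^2) * es) * shiftSD
  if (outlier) {
    x <- c(x, outlierShift[1])
    y <- c(y, outlierShift[2])
  }
  ids <- sprintf("pos%02d", seq_along(x))
  singles <- data.frame(
    constructId = ids, v12 = wt$v12 + x, v12SE = 0.8,
    slope = 10.5, slopeSE = 0.3, n = 6L, role = "mutant",
    temperature = 291.15)
  doubles <- data.frame(
    constructId = paste0("K1237E/", ids), v12 = bg$v12 + y, v12SE = 0.9,
    slope = 10.8, slopeSE = 0.4, n = 6L, role = "double",
    temperature = 291.15)
  rbind(base[base$role %in% c("reference", "background"), ],
        singles, doubles)
}
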