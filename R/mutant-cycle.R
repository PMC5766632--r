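#' @include fit-boltzmann.R
NULL

#' Free energy of inactivation from Boltzmann parameters
#'
#' `deltaG = z F V1/2` in kcal/mol (`F` = 23.061 kcal mol^-1 V^-1, `V1/2`
#' converted from mV to volts). The standard error uses relative-error
#' propagation, `SE = |deltaG| sqrt((SE_z/z)^2 + (SE_V12/V12)^2)`, with the
#' magnitude taken so the SE is non-negative. When `V1/2 = 0` exactly the
#' relative term is undefined; the absolute first-order propagation
#' `SE = z F SE_V12` is reported instead and flagged.
#'
#' @param fit a [BoltzmannFit-class], or `NULL` if the printed parameters
#'   are supplied directly via the remaining arguments.
#' @param constructId construct name carried on the result.
#' @param v12,v12SE,k,kSE,temperature parameter override: midpoint and slope
#'   factor (mV) with standard errors and temperature (K). Used when
#'   `fit` is `NULL`, e.g. to work from published parameter tables.
#' @return a [FreeEnergy-class].
#' @export
freeEnergy <- function(fit = NULL, constructId = "construct",
                       v12 = NULL, v12SE = NULL, k = NULL, kSE = NULL,
                       temperature = 291.15) {
  if (!is.null(fit)) {
    stopifnot(is(fit, "BoltzmannFit"))
    v12 <- fit@v12; v12SE <- fit@v12SE
    z <- fit@z; zSE <- fit@zSE
    temperature <- fit@temperature
  } else {
    stopifnot(!is.null(v12), !is.null(k), k > 0)
    if (is.null(v12SE)) v12SE <- 0
    if (is.null(kSE)) kSE <- 0
    z <- rtfMillivolts(temperature) / k
    zSE <- z * kSE / k
  }
  dG <- z * .FARADAY_KCAL * (v12 / 1000)
  flags <- character()
  if (v12 == 0) {
    se <- z * .FARADAY_KCAL * (v12SE / 1000)
    flags <- "abs_se_fallback"
  } else {
    se <- abs(dG) * sqrt((zSE / z)^2 + (v12SE / v12)^2)
  }
  new("FreeEnergy", constructId = constructId, deltaG = dG, se = se,
      temperature = temperature, flags = flags)
}

#' Double-mutant-cycle coupling energy
#'
#' `ddG = (dG_MUT1 - dG_WT) - (dG_MUT1/MUT2 - dG_MUT2)`. Additivity of the
#' two single-mutant perturbations gives `ddG = 0`; `|ddG|` above the
#' threshold (1 kcal/mol by convention) is read as direct molecular
#' coupling. The default standard error is the quadrature of the two
#' single-mutant SEs, as conventionally reported; `seMode = "full"`
#' propagates all four constructs' SEs instead.
#'
#' @param wt,mut1,mut2,double [FreeEnergy-class] objects for the wild type,
#'   the two single mutants and the double mutant, all at the same
#'   temperature.
#' @param threshold direct-coupling criterion, kcal/mol.
#' @param seMode `"printed"` or `"full"`.
#' @return a [CycleResult-class].
#' @export
couplingEnergy <- function(wt, mut1, mut2, double, threshold = 1,
                           seMode = c("printed", "full")) {
  seMode <- match.arg(seMode)
  for (fe in list(wt, mut1, mut2, double)) stopifnot(is(fe, "FreeEnergy"))
  temps <- vapply(list(wt, mut1, mut2, double), temperatureK, numeric(1))
  if (diff(range(temps)) > 1e-9)
    stop("all four constructs must share one temperature; got ",
         paste(unique(temps), collapse = ", "), " K")
  ddG <- (deltaG(mut1) - deltaG(wt)) - (deltaG(double) - deltaG(mut2))
  se <- switch(seMode,
    printed = sqrt(standardError(mut1)^2 + standardError(mut2)^2),
    full = sqrt(sum(vapply(list(wt, mut1, mut2, double),
                           function(f) standardError(f)^2, numeric(1)))))
  new("CycleResult",
      ids = c(wt = constructId(wt), mut1 = constructId(mut1),
              mut2 = constructId(mut2), double = constructId(double)),
      deltaDeltaG = ddG, se = se, seMode = seMode,
      threshold = threshold, coupled = abs(ddG) > threshold)
}

#' Mutant-cycle screen over a fit table
#'
#' Evaluates one double-mutant cycle per S6 single mutant against a shared
#' background mutation. The double mutant of `mut` is looked up as
#' `"<background>/<mut>"` or `"<mut>/<background>"`; mutants whose double is
#' absent from the table (e.g. non-expressing constructs) are skipped with a
#' logged reason.
#'
#' @param fits fit table as produced by [fitTable()] (columns `constructId`,
#'   `v12`, `v12SE`, `slope`, `slopeSE`, `temperature`).
#' @param backgroundId the shared background mutation (MUT2).
#' @param referenceId the wild-type reference.
#' @param threshold,seMode passed to [couplingEnergy()].
#' @param sep separator used in double-mutant ids.
#' @return data.frame with one row per complete quartet: `mutant`, `double`,
#'   `ddG`, `se`, `coupled`; skipped mutants are in attribute `"skipped"`
#'   and the number of coupled positions in attribute `"nCoupled"`.
#' @export
cycleScreen <- function(fits, backgroundId, referenceId, threshold = 1,
                        seMode = "printed", sep = "/") {
  ids <- fits$constructId
  if (!referenceId %in% ids) stop("reference construct '", referenceId,
                                  "' missing from the fit table")
  if (!backgroundId %in% ids) stop("background construct '", backgroundId,
                                   "' missing from the fit table")
  feOf <- function(id) {
    r <- fits[fits$constructId == id, ][1, ]
    freeEnergy(constructId = id, v12 = r$v12, v12SE = r$v12SE,
               k = r$slope, kSE = r$slopeSE, temperature = r$temperature)
  }
  wt <- feOf(referenceId); bg <- feOf(backgroundId)
  isDouble <- grepl(sep, ids, fixed = TRUE)
  singles <- setdiff(ids[!isDouble], c(referenceId, backgroundId))
  skipped <- character()
  rows <- list()
  for (m in singles) {
    cand <- c(paste(backgroundId, m, sep = sep), paste(m, backgroundId, sep = sep))
    dbl <- cand[cand %in% ids]
    if (!length(dbl)) {
      skipped[m] <- "double mutant not in fit table (e.g. did not express)"
      next
    }
    res <- couplingEnergy(wt, feOf(m), bg, feOf(dbl[1]),
                          threshold = threshold, seMode = seMode)
    rows[[m]] <- data.frame(mutant = m, double = dbl[1],
                            ddG = deltaG(res), se = standardError(res),
                            coupled = isCoupled(res))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mutant = character(), double = character(),
               ddG = numeric(), se = numeric(), coupled = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "nCoupled") <- sum(out$coupled)
  out
}
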