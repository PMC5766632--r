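#' @include scenarios.R
NULL

#' Generate a construct library of peak-current datasets
#'
#' Turns a construct-parameter table (see [constructScenario()]) into
#' replicate-level [PeakSeries-class] datasets via the phenomenological
#' generator. Each construct draws its noise from an independent stream
#' derived from the master seed and the construct id by stable hashing, so
#' adding constructs does not reshuffle existing data.
#'
#' @param params construct table: columns `constructId`, `v12`, `slope`,
#'   `role` (exactly one `reference`), optionally `temperature`; or a list
#'   of [PhenoParams-class] plus a `roles` attribute.
#' @param protocols character subset of `c("ssi", "recovery", "activation")`.
#' @param sigma replicate noise SD (normalized-current units); 0 for
#'   noiseless single-replicate data.
#' @param nReplicates replicates per construct.
#' @param seed master seed.
#' @param ssiGrid conditioning voltages, mV.
#' @param recoveryGrid recovery intervals, ms.
#' @param recoveryClass recovery component class for constructs that carry
#'   recovery parameters.
#' @param activationGrid step potentials, mV.
#' @return named list (by construct id) of lists of [PeakSeries-class], one
#'   entry per requested protocol the construct supports; the parameter
#'   table is attached as attribute `"params"`.
#' @export
makeConstructLibrary <- function(params, protocols = "ssi", sigma = 0.02,
                                 nReplicates = 7, seed = 1L,
                                 ssiGrid = seq(-120, -10, by = 5),
                                 recoveryGrid = 10^seq(log10(0.1), 4,
                                                       length.out = 36),
                                 recoveryClass = "p100ms",
                                 activationGrid = seq(-100, 70, by = 10)) {
  stopifnot(all(protocols %in% c("ssi", "recovery", "activation")))
  if (is.data.frame(params)) {
    tab <- params
    if (anyDuplicated(tab$constructId))
      stop("duplicate construct ids: ",
           paste(unique(tab$constructId[duplicated(tab$constructId)]),
                 collapse = ", "))
    if (sum(tab$role == "reference") != 1L)
      stop("exactly one construct must have role 'reference'")
    phenos <- lapply(seq_len(nrow(tab)), function(i) {
      rec <- list()
      if ("recovery" %in% protocols) {
        rs <- recoveryScenario()
        rs <- rs[rs$constructId == tab$constructId[i], ]
        if (nrow(rs))
          rec <- lapply(split(rs, rs$class), function(d)
            data.frame(amplitude = d$amplitude, tau = d$tau))
      }
      PhenoParams(constructId = tab$constructId[i],
                  inactV12 = tab$v12[i], inactSlope = tab$slope[i],
                  recovery = rec,
                  actV12 = if ("actV12" %in% names(tab)) tab$actV12[i] else NA,
                  actSlope = if ("actSlope" %in% names(tab)) tab$actSlope[i] else NA,
                  actReversal = if ("actReversal" %in% names(tab)) tab$actReversal[i] else NA)
    })
  } else {
    phenos <- params
    tab <- attr(params, "params")
    ids <- vapply(phenos, function(p) p@constructId, character(1))
    if (anyDuplicated(ids)) stop("duplicate construct ids")
  }
  temperatures <- if (!is.null(tab) && "temperature" %in% names(tab))
    tab$temperature else rep(291.15, length(phenos))
  lib <- stats::setNames(vector("list", length(phenos)),
                         vapply(phenos, function(p) p@constructId,
                                character(1)))
  for (i in seq_along(phenos)) {
    p <- phenos[[i]]
    out <- list()
    for (proto in protocols) {
      series <- switch(proto,
        ssi = genPhenoSeries(p, "ssi", ssiGrid,
                             temperature = temperatures[i]),
        recovery = {
          if (is.null(p@recovery[[recoveryClass]])) NULL
          else genPhenoSeries(p, "recovery", recoveryGrid,
                              recoveryClass = recoveryClass,
                              temperature = temperatures[i])
        },
        activation = {
          if (!is.finite(p@actV12)) NULL
          else genPhenoSeries(p, "activation", activationGrid,
                              temperature = temperatures[i])
        })
      if (is.null(series)) next
      if (sigma > 0 || nReplicates > 1) {
        series <- addNoise(series, sigma = sigma, nReplicates = nReplicates,
                           seed = constructSeed(seed,
                                                paste0(p@constructId, ":",
                                                       proto)))
      }
      out[[proto]] <- series
    }
    lib[[i]] <- out
  }
  attr(lib, "params") <- tab
  attr(lib, "seed") <- seed
  lib
}

#' Default shipped construct library
#'
#' The oocyte quartet scenario (wild type, I1575C, K1237E and the double
#' mutant) generated with the default protocols and noise.
#'
#' @inheritParams makeConstructLibrary
#' @param scenario scenario name passed to [constructScenario()].
#' @return as [makeConstructLibrary()].
#' @export
defaultConstructLibrary <- function(scenario = "oocyte-quartet",
                                    protocols = "ssi", sigma = 0.02,
                                    nReplicates = 7, seed = 1L, ...) {
  makeConstructLibrary(constructScenario(scenario), protocols = protocols,
                       sigma = sigma, nReplicates = nReplicates, seed = seed,
                       ...)
}
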