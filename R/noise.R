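#' @include AllClasses.R
NULL

#' Stable 31-bit string hash
#'
#' Deterministic polynomial hash of a string, used to derive per-construct
#' random-number streams from a single master seed so that adding constructs
#' to a library never reshuffles the data of existing ones.
#'
#' @param x character vector.
#' @return integer vector in `[0, 2^31 - 2]`.
#' @export
stableHash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-construct seed derived from a master seed
#'
#' @param masterSeed integer master seed.
#' @param constructId construct name (and optionally a stream tag appended
#'   by the caller, e.g. `"wt:ssi"`).
#' @return integer seed below 2^31.
#' @export
constructSeed <- function(masterSeed, constructId) {
  as.integer((as.numeric(masterSeed) %% 2147483647 + stableHash(constructId)) %%
               2147483647)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Add replicate-level Gaussian noise to a peak series
#'
#' Additive Gaussian noise on normalized peak currents, independently per
#' point and replicate, emulating the replicate scatter behind reported
#' means and standard errors. Deterministic under a fixed seed; with
#' `sigma = 0` the noiseless per-point means are simply replicated.
#'
#' @param series a [PeakSeries-class]; its per-point replicate means are the
#'   noiseless base.
#' @param sigma noise standard deviation, normalized-current units.
#' @param nReplicates number of replicates to generate.
#' @param seed integer seed.
#' @return a [PeakSeries-class] with `nReplicates` rows.
#' @export
addNoise <- function(series, sigma = 0.02, nReplicates = 7, seed = 1L) {
  stopifnot(is(series, "PeakSeries"), sigma >= 0, nReplicates >= 1)
  base <- seriesMeans(series)
  y <- matrix(rep(base, each = nReplicates), nrow = nReplicates)
  if (sigma > 0) {
    noise <- .withSeed(seed,
      matrix(stats::rnorm(nReplicates * length(base), sd = sigma),
             nrow = nReplicates))
    y <- y + noise
  }
  new("PeakSeries",
      constructId = series@constructId, protocolKind = series@protocolKind,
      x = series@x, y = y, temperature = series@temperature)
}
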