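#' @include fit-boltzmann.R
NULL

#' Midpoint shift table relative to a reference construct
#'
#' `shift = V1/2(construct) - V1/2(reference)` with the SE in quadrature and
#' a two-tailed Student's t-test (pooled variance) computed from the group
#' summary statistics: group SDs are reconstructed as `SE * sqrt(n)`. A
#' missing group size leaves the p-value `NA` with a warning.
#'
#' @param fits fit table (see [fitTable()]); needs columns `constructId`,
#'   `v12`, `v12SE`, `n`.
#' @param referenceId reference construct id.
#' @param background label stored on the table (which background the fits
#'   were measured in).
#' @return data.frame with columns `constructId`, `shift` (mV), `shiftSE`,
#'   `t`, `df`, `p`, `n`, `background`.
#' @export
shiftTable <- function(fits, referenceId, background = referenceId) {
  if (!referenceId %in% fits$constructId)
    stop("reference construct '", referenceId, "' missing")
  ref <- fits[fits$constructId == referenceId, ][1, ]
  out <- do.call(rbind, lapply(seq_len(nrow(fits)), function(i) {
    r <- fits[i, ]
    shift <- r$v12 - ref$v12
    se <- sqrt(r$v12SE^2 + ref$v12SE^2)
    n1 <- r$n; n2 <- ref$n
    if (identical(r$constructId, ref$constructId)) {
      t <- 0; df <- if (is.na(n1)) NA_real_ else 2 * n1 - 2; p <- 1
    } else if (is.na(n1) || is.na(n2)) {
      warning("group size missing for '", r$constructId,
              "'; p-value omitted", call. = FALSE)
      t <- NA_real_; df <- NA_real_; p <- NA_real_
    } else {
      s1 <- r$v12SE * sqrt(n1); s2 <- ref$v12SE * sqrt(n2)
      df <- n1 + n2 - 2
      sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
      denom <- sp * sqrt(1 / n1 + 1 / n2)
      t <- if (denom == 0) { if (shift == 0) 0 else Inf * sign(shift) }
           else shift / denom
      p <- 2 * stats::pt(-abs(t), df)
    }
    data.frame(constructId = r$constructId, shift = shift, shiftSE = se,
               t = t, df = df, p = p, n = n1, background = background)
  }))
  rownames(out) <- NULL
  out
}

#' Strip a background prefix from double-mutant ids
#'
#' Maps `"K1237E/I1575C"` to `"I1575C"` so that shift tables computed in
#' two backgrounds can be joined position by position.
#'
#' @param ids character vector of construct ids.
#' @param backgroundId background mutation name.
#' @param sep separator used in double-mutant ids.
#' @return ids with the background component removed.
#' @export
stripBackground <- function(ids, backgroundId, sep = "/") {
  parts <- strsplit(ids, sep, fixed = TRUE)
  vapply(parts, function(p) {
    q <- setdiff(p, backgroundId)
    if (length(q)) paste(q, collapse = sep) else backgroundId
  }, character(1))
}

## Pearson correlation with an explicit degenerate-axis check.
.pearson <- function(x, y, labels = c("x", "y")) {
  if (stats::sd(x) == 0)
    stop("correlation undefined: '", labels[1], "' axis is constant")
  if (stats::sd(y) == 0)
    stop("correlation undefined: '", labels[2], "' axis is constant")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

## Join two shift tables on constructId, dropping reference self-rows.
.pairShifts <- function(shiftsX, shiftsY, exclude = character()) {
  x <- shiftsX[!(shiftsX$constructId %in% unique(shiftsX$background)), ]
  y <- shiftsY[!(shiftsY$constructId %in% unique(shiftsY$background)), ]
  m <- merge(x[, c("constructId", "shift")], y[, c("constructId", "shift")],
             by = "constructId", suffixes = c(".x", ".y"))
  excluded <- m$constructId[m$constructId %in% exclude]
  names(excluded) <- rep("excluded by request", length(excluded))
  m <- m[!m$constructId %in% exclude, ]
  list(pairs = m, excluded = excluded)
}

#' Correlation of mutation-induced shifts across two backgrounds
#'
#' Pearson correlation (with a two-tailed test) between the midpoint shifts
#' produced by the same mutations in two mutational backgrounds, with an
#' explicit exclusion list (outlier exclusion is never automatic).
#'
#' @param shiftsWt shift table in the wild-type background.
#' @param shiftsBg shift table in the mutant background, with construct ids
#'   already mapped to positions (see [stripBackground()]).
#' @param exclude construct ids excluded from the regression.
#' @return a [CorrelationResult-class].
#' @export
backgroundCorrelation <- function(shiftsWt, shiftsBg, exclude = character()) {
  pr <- .pairShifts(shiftsWt, shiftsBg, exclude)
  m <- pr$pairs
  if (nrow(m) < 3L)
    stop("fewer than 3 shared constructs after exclusion")
  res <- .pearson(m$shift.x, m$shift.y,
                  labels = c("wild-type background", "mutant background"))
  new("CorrelationResult", r = res$r, p = res$p, nUsed = nrow(m),
      excluded = pr$excluded,
      slope = res$slope, intercept = res$intercept)
}

#' Advisory leave-one-out outlier flags for paired shifts
#'
#' Jackknife on the Pearson correlation: a point whose removal increases R
#' by more than `delta` is flagged. Flags are advisory only and never
#' applied automatically; reproducible analyses must pass explicit
#' exclusion lists to [backgroundCorrelation()].
#'
#' @param shiftsX,shiftsY shift tables sharing construct ids.
#' @param delta flagging threshold on the increase in R.
#' @return data.frame with columns `constructId`, `rWithout`, `deltaR`,
#'   `flagged`.
#' @export
flagOutliers <- function(shiftsX, shiftsY, delta = 0.15) {
  m <- .pairShifts(shiftsX, shiftsY)$pairs
  if (nrow(m) < 5L) stop("need at least 5 pairs")
  rFull <- .pearson(m$shift.x, m$shift.y)$r
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    r <- .pearson(m$shift.x[-i], m$shift.y[-i])$r
    data.frame(constructId = m$constructId[i], rWithout = r,
               deltaR = r - rFull, flagged = (r - rFull) > delta)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between activation and inactivation shifts
#'
#' Tests whether mutation-induced shifts of the inactivation midpoint track
#' shifts of the activation midpoint across constructs (they should not if
#' the inactivation perturbations are not secondary to activation).
#'
#' @param inactShifts,actShifts shift tables sharing construct ids.
#' @param exclude construct ids excluded from the regression.
#' @return a [CorrelationResult-class].
#' @export
pairedShiftCorrelation <- function(inactShifts, actShifts,
                                   exclude = character()) {
  pr <- .pairShifts(inactShifts, actShifts, exclude)
  m <- pr$pairs
  if (nrow(m) < 3L) stop("fewer than 3 shared constructs")
  res <- .pearson(m$shift.x, m$shift.y,
                  labels = c("inactivation shift", "activation shift"))
  new("CorrelationResult", r = res$r, p = res$p, nUsed = nrow(m),
      excluded = pr$excluded,
      slope = res$slope, intercept = res$intercept)
}
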