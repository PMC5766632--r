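#' @include AllClasses.R
NULL

#' Write peak series to the shared CSV dialect
#'
#' Long-format CSV with columns `construct_id`, `protocol_kind`,
#' `replicate`, `x`, `y`, plus a JSON sidecar (`<path>.json`) carrying the
#' temperature and any provenance fields supplied in `meta`.
#'
#' @param series a [PeakSeries-class] or a list of them.
#' @param path output CSV path.
#' @param meta named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
writePeakSeries <- function(series, path, meta = list()) {
  if (is(series, "PeakSeries")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    y <- peakMatrix(s)
    data.frame(
      construct_id = constructId(s), protocol_kind = protocolKind(s),
      replicate = rep(seq_len(nrow(y)), times = ncol(y)),
      x = rep(xValues(s), each = nrow(y)),
      y = as.vector(y))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(
    temperature = vapply(series, temperatureK, numeric(1)),
    construct_id = vapply(series, constructId, character(1))), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read peak series from the shared CSV dialect
#'
#' Accepts the dialect written by [writePeakSeries()] and also bare
#' pre-normalized tables with columns `x`, `y` and optionally `replicate`.
#'
#' @param path CSV path.
#' @param temperature used when no sidecar is present, K.
#' @return a named list of [PeakSeries-class] objects.
#' @export
readPeakSeries <- function(path, temperature = 291.15) {
  tab <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(tab)))
    stop("peak-series CSV needs at least columns 'x' and 'y'")
  if (!"construct_id" %in% names(tab)) tab$construct_id <- "series"
  if (!"protocol_kind" %in% names(tab)) tab$protocol_kind <- "ssi"
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  side <- paste0(path, ".json")
  temps <- NULL
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(sc$temperature))
      temps <- stats::setNames(sc$temperature, sc$construct_id)
  }
  out <- lapply(split(tab, tab$construct_id), function(d) {
    x <- sort(unique(d$x))
    reps <- sort(unique(d$replicate))
    y <- matrix(NA_real_, length(reps), length(x))
    for (i in seq_along(reps)) {
      di <- d[d$replicate == reps[i], ]
      y[i, match(di$x, x)] <- di$y
    }
    if (anyNA(y)) stop("incomplete replicate-by-x grid in ", path)
    tk <- if (!is.null(temps) && d$construct_id[1] %in% names(temps))
      unname(temps[d$construct_id[1]]) else temperature
    new("PeakSeries", constructId = as.character(d$construct_id[1]),
        protocolKind = as.character(d$protocol_kind[1]),
        x = x, y = y, temperature = tk)
  })
  out
}
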