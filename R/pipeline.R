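#' @include library.R mutant-cycle.R screen.R io.R
NULL

#' Default pipeline configuration
#'
#' @param scenario name of a shipped scenario ([constructScenario()]), the
#'   synthetic cysteine-scanning screen (`"screen"`, see
#'   [screenScenario()]), or a construct-parameter data.frame. The default
#'   is the screen, which exercises every stage: fits, cycles and the
#'   background correlation.
#' @param protocols protocols to simulate.
#' @param sigma,nReplicates,seed noise model and master seed.
#' @param referenceId,backgroundId reference (wild type) and background
#'   construct ids; `backgroundId = NA` disables the cycle and
#'   background-correlation stages.
#' @param exclusions construct ids excluded from the background regression.
#' @param threshold direct-coupling criterion, kcal/mol.
#' @param outputDir directory for [writeReport()].
#' @param format `"tsv"`, `"json"` or both.
#' @return a named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(scenario = "screen", protocols = "ssi",
                           sigma = 0.02, nReplicates = 7, seed = 1L,
                           referenceId = "wt", backgroundId = "K1237E",
                           exclusions = character(), threshold = 1,
                           outputDir = "gating-report",
                           format = c("tsv", "json")) {
  list(scenario = scenario, protocols = protocols, sigma = sigma,
       nReplicates = nReplicates, seed = seed, referenceId = referenceId,
       backgroundId = backgroundId, exclusions = exclusions,
       threshold = threshold, outputDir = outputDir, format = format)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file; unknown keys are rejected.
#' @return a config list as from [pipelineConfig()].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, raw)
}

## Validate a config against the resolved construct table; collect every
## problem and report them at once.
.validateConfig <- function(config, tab) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(config$sigma) && config$sigma >= 0, "sigma must be >= 0")
  chk(is.numeric(config$nReplicates) && config$nReplicates >= 1,
      "nReplicates must be >= 1")
  chk(all(config$protocols %in% c("ssi", "recovery", "activation")),
      "protocols must be among ssi, recovery, activation")
  chk(config$referenceId %in% tab$constructId,
      sprintf("reference construct '%s' not in the library", config$referenceId))
  if (!is.na(config$backgroundId))
    chk(config$backgroundId %in% tab$constructId,
        sprintf("background construct '%s' not in the library",
                config$backgroundId))
  missingExcl <- setdiff(config$exclusions, tab$constructId)
  chk(length(missingExcl) == 0,
      sprintf("excluded construct(s) not in the library: %s",
              paste(missingExcl, collapse = ", ")))
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' simulate -> process -> fit -> cycle -> screen, deterministic under the
#' config's master seed. Constructs whose fit fails are logged and skipped;
#' the pipeline continues with the remainder.
#'
#' @param config list from [pipelineConfig()] or [loadConfig()].
#' @return a report bundle: list with `fits` (fit table), `shiftsReference`,
#'   `shiftsBackground` (shift tables), `cycles` (cycle table),
#'   `correlation` ([CorrelationResult-class] or `NULL`), `recovery`
#'   (recovery fit table or `NULL`), `log` (stage log data.frame) and
#'   `configHash`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  tab <- if (is.data.frame(config$scenario)) config$scenario
         else if (identical(config$scenario, "screen"))
           screenScenario(seed = as.integer(config$seed))
         else constructScenario(config$scenario)
  .validateConfig(config, tab)
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, detail = detail)
  }
  note("config", sprintf("seed=%d sigma=%g nReplicates=%d",
                         as.integer(config$seed), config$sigma,
                         as.integer(config$nReplicates)))

  lib <- makeConstructLibrary(tab, protocols = config$protocols,
                              sigma = config$sigma,
                              nReplicates = config$nReplicates,
                              seed = config$seed)
  note("simulate", sprintf("%d constructs, protocols: %s", length(lib),
                           paste(config$protocols, collapse = ",")))

  fits <- list(); failed <- character()
  for (id in names(lib)) {
    s <- lib[[id]]$ssi
    if (is.null(s)) next
    f <- try(fitBoltzmann(s), silent = TRUE)
    if (inherits(f, "try-error")) {
      failed <- c(failed, id)
      note("fit-ssi", sprintf("FAILED %s: %s", id,
                              conditionMessage(attr(f, "condition"))))
    } else fits[[id]] <- f
  }
  if (!length(fits)) stop("no construct produced a usable availability fit")
  ft <- fitTable(fits, n = tab$n[match(names(fits), tab$constructId)])
  note("fit-ssi", sprintf("%d fits, %d failures", nrow(ft), length(failed)))

  recTab <- NULL
  if ("recovery" %in% config$protocols) {
    recRows <- list()
    for (id in names(lib)) {
      s <- lib[[id]]$recovery
      if (is.null(s)) next
      sel <- try(chooseRecoveryOrder(s, "p100ms"), silent = TRUE)
      if (inherits(sel, "try-error")) {
        note("fit-recovery", sprintf("FAILED %s", id)); next
      }
      cf <- coef(sel$fit)
      recRows[[id]] <- data.frame(constructId = id, order = sel$order,
                                  t(cf))
    }
    if (length(recRows)) {
      nm <- unique(unlist(lapply(recRows, names)))
      recTab <- do.call(rbind, lapply(recRows, function(r) {
        r[setdiff(nm, names(r))] <- NA_real_; r[nm]
      }))
      rownames(recTab) <- NULL
    }
    note("fit-recovery", sprintf("%d recovery fits", length(recRows)))
  }

  shiftsRef <- shiftTable(ft, config$referenceId,
                          background = config$referenceId)
  shiftsBg <- NULL; cycles <- NULL; correlation <- NULL
  if (!is.na(config$backgroundId) && config$backgroundId %in% ft$constructId) {
    cycles <- cycleScreen(ft, backgroundId = config$backgroundId,
                          referenceId = config$referenceId,
                          threshold = config$threshold)
    note("cycle", sprintf("%d quartets, %d coupled, %d skipped",
                          nrow(cycles), attr(cycles, "nCoupled"),
                          length(attr(cycles, "skipped"))))
    isDouble <- grepl("/", ft$constructId, fixed = TRUE)
    bgFits <- ft[isDouble | ft$constructId == config$backgroundId, ]
    if (nrow(bgFits) >= 2) {
      bgFits$constructId <- stripBackground(bgFits$constructId,
                                            config$backgroundId)
      shiftsBg <- shiftTable(bgFits, config$backgroundId,
                             background = config$backgroundId)
      corTry <- try(backgroundCorrelation(shiftsRef, shiftsBg,
                                          exclude = config$exclusions),
                    silent = TRUE)
      if (!inherits(corTry, "try-error")) {
        correlation <- corTry
        note("screen", sprintf("R=%.3f P=%.3g n=%d", correlation@r,
                               correlation@p, correlation@nUsed))
      } else note("screen", "background correlation unavailable")
    }
  }

  bundle <- list(fits = ft, shiftsReference = shiftsRef,
                 shiftsBackground = shiftsBg, cycles = cycles,
                 correlation = correlation, recovery = recTab,
                 failed = failed,
                 log = do.call(rbind, log),
                 configHash = stableHash(paste(deparse(config), collapse = "")))
  bundle
}

## Round all numeric columns to a fixed number of significant digits.
.signifCols <- function(d, digits = 6) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], digits)
  d
}

#' Write a report bundle to disk
#'
#' Writes each table of the bundle as TSV and/or a single JSON document,
#' with stable column order and numbers serialized to 6 significant digits.
#' Empty tables produce headers-only files.
#'
#' @param bundle result of [runPipeline()].
#' @param outputDir output directory (created if needed).
#' @param format subset of `c("tsv", "json")`.
#' @return character vector of files written, invisibly.
#' @export
writeReport <- function(bundle, outputDir = "gating-report",
                        format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(fits = bundle$fits,
                 shifts_reference = bundle$shiftsReference,
                 shifts_background = bundle$shiftsBackground,
                 cycles = bundle$cycles,
                 recovery = bundle$recovery,
                 log = bundle$log)
  if (!is.null(bundle$correlation)) {
    cr <- bundle$correlation
    tables$correlation <- data.frame(
      r = cr@r, p = cr@p, nUsed = cr@nUsed,
      excluded = paste(cr@excluded, collapse = ","),
      slope = cr@slope, intercept = cr@intercept)
  }
  tables <- Filter(Negate(is.null), tables)
  files <- character()
  if ("tsv" %in% format) {
    for (nm in names(tables)) {
      f <- file.path(outputDir, paste0(nm, ".tsv"))
      utils::write.table(.signifCols(tables[[nm]]), f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  if ("json" %in% format) {
    doc <- lapply(tables, .signifCols)
    doc$configHash <- bundle$configHash
    f <- file.path(outputDir, "report.json")
    jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    files <- c(files, f)
  }
  invisible(files)
}
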