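## CSV / YAML / JSON I/O and the end-to-end pipeline.
##
## All tabular artifacts are UTF-8 CSV with '.' decimal; missing dye
## intensities are written as empty fields. Summaries are JSON; configuration
## is a YAML file.

#' Write and read event tables
#'
#' CSV with exactly the event-table column names; `NA` dye intensities (NK
#' rows) are encoded as empty fields. `readEvents()` validates the schema
#' (a missing mandatory column is a schema error naming it), reports the
#' first unparseable row, and preserves any extra columns.
#'
#' @param events an [EventTable].
#' @param path file path.
#' @return `readEvents()` returns an [EventTable]; `writeEvents()` returns
#'   `path` invisibly.
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stopInput("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(EVENT_COLUMNS, colnames(df))
  if (length(missing))
    stopSchema("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df$dye_log_intensity <- suppressWarnings(as.numeric(df$dye_log_intensity))
  df$day <- suppressWarnings(as.numeric(df$day))
  dead <- df$dead
  if (!is.logical(dead)) {
    dead <- toupper(trimws(as.character(dead)))
    parsed <- rep(NA, length(dead))
    parsed[dead %in% c("TRUE", "T", "1")] <- TRUE
    parsed[dead %in% c("FALSE", "F", "0")] <- FALSE
    dead <- parsed
  }
  bad <- which(is.na(dead) | is.na(df$day))
  if (length(bad))
    stopInput("unparseable row ", bad[1], " in ", path,
              " (dead/day could not be interpreted)")
  df$dead <- dead
  if ("true_generation" %in% colnames(df))
    df$true_generation <- suppressWarnings(as.integer(df$true_generation))
  out <- try(new("EventTable", DataFrame(df)), silent = TRUE)
  if (inherits(out, "try-error"))
    stopSchema("invalid event table: ", attr(out, "condition")$message)
  out
}

#' Write and read killing tables
#'
#' @param kt a [KillingTable].
#' @param path file path.
#' @return `readKillingTable()` returns a [KillingTable].
#' @export
writeKillingTable <- function(kt, path) {
  utils::write.csv(as.data.frame(kt), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeKillingTable
#' @export
readKillingTable <- function(path) {
  if (!file.exists(path)) stopInput("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(KILLING_COLUMNS, colnames(df))
  if (length(missing))
    stopSchema("missing mandatory column(s): ", paste(missing, collapse = ", "))
  out <- try(new("KillingTable", DataFrame(df)), silent = TRUE)
  if (inherits(out, "try-error"))
    stopSchema("invalid killing table: ", attr(out, "condition")$message)
  out
}

#' Read a pipeline configuration
#'
#' YAML with blocks: `simulate` (fields of [simConfig()]; `generation_dist`,
#' `background_death` and `kill_means` may be omitted to use the calibration
#' defaults) or `events` (path to an existing event CSV); `gmax`; and
#' `inference` (`chains`, `warmup`, `kept`, `seed`, `epsilon` and a list of
#' `contrasts`, each with `name`, `type` in `stratum`/`target`/`day`, and
#' `effector`/`target` as the type requires).
#'
#' @param path YAML file.
#' @return the resolved configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopInput("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  resolvePipelineConfig(cfg)
}

resolvePipelineConfig <- function(cfg) {
  if (is.null(cfg$events) && is.null(cfg$simulate))
    stopConfig("config must declare either `events` (path) or a `simulate` block")
  cfg$gmax <- cfg$gmax %||% 6L
  inf <- cfg$inference %||% list()
  inf$chains <- inf$chains %||% 4L
  inf$warmup <- inf$warmup %||% 2500L
  inf$kept <- inf$kept %||% 2500L
  inf$epsilon <- inf$epsilon %||% 0.005
  if (!is.null(cfg$simulate) || length(inf$contrasts %||% list())) {
    if (is.null(inf$seed) && is.null(cfg$simulate$seed))
      stopConfig("a seed is required whenever a stochastic stage runs")
  }
  inf$seed <- inf$seed %||% cfg$simulate$seed %||% 1L
  cfg$inference <- inf
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simConfigFromList <- function(block) {
  args <- list(
    nDonors = block$n_donors %||% 14L,
    cellsPerPopulation = block$cells_per_population %||% 20000L,
    nkEventsPerPopulation = block$nk_events_per_population %||% 5000L,
    dyeMu0 = block$dye_mu0 %||% 4.5,
    dyeSigma = block$dye_sigma %||% 0.08,
    donorSdLogit = block$donor_sd_logit %||% 0.15,
    wellSdLogit = block$well_sd_logit %||% 0.10,
    nkDeathRate = block$nk_death_rate %||% 0.05,
    seed = block$seed %||% 1L)
  args$dayAssignment <- block$day_assignment %||%
    c(rep(2.5, ceiling(args$nDonors * 10 / 14)),
      rep(3.5, args$nDonors - ceiling(args$nDonors * 10 / 14)))
  if (!is.null(block$generation_dist)) args$generationDist <- block$generation_dist
  if (!is.null(block$background_death)) args$backgroundDeath <- block$background_death
  if (!is.null(block$kill_means)) args$killMeans <- block$kill_means
  do.call(simConfig, args)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                        class = c("nkassay_stage_error", "error")))
  })
}

#' Run the full assay analysis pipeline
#'
#' Simulate (or read) an event table, deconvolve dye generations, build the
#' stratified specific-killing table, fit the declared Beta-regression
#' contrasts and write all artifacts under `outDir`: `records.csv`,
#' `draws_<contrast>.csv`, and `summary.json` (which embeds the fully
#' resolved configuration, stage log counts and per-contrast posterior
#' summaries). Identical configuration and seed give identical outputs. Any
#' stage error is fatal and is re-raised with the stage name.
#'
#' @param config a configuration list (see [readPipelineConfig()]) or a path
#'   to a YAML file.
#' @param outDir output directory (created if needed).
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else resolvePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list()

  events <- withStage("events", {
    if (!is.null(cfg$events)) readEvents(cfg$events)
    else simulatePanel(simConfigFromList(cfg$simulate))
  })
  log$events_read <- nrow(events)
  if (isTRUE(cfg$write_events))
    withStage("events", writeEvents(events, file.path(outDir, "events.csv")))

  dec <- withStage("proliferation", deconvolveGenerations(events, gMax = cfg$gmax))
  log$peak_models_fitted <- length(dec$models)
  log$peak_models_nonconverged <-
    sum(!vapply(dec$models, isConverged, logical(1)))

  kt <- withStage("killing", buildKillingTable(events, dec$generations))
  writeKillingTable(kt, file.path(outDir, "records.csv"))
  log$killing_records <- nrow(kt)

  inf <- cfg$inference
  summaries <- list()
  nClamped <- 0L
  for (ct in inf$contrasts %||% list()) {
    nm <- ct$name %||% paste(ct$type, ct$effector %||% "", ct$target %||% "",
                             sep = "_")
    res <- withStage(paste0("inference:", nm), {
      rd <- switch(ct$type,
        stratum = contrastStratum(kt, ct$effector, ct$target, inf$epsilon),
        target = contrastTarget(kt, ct$effector, inf$epsilon),
        day = contrastSpontaneousDay(events, ct$target, inf$epsilon),
        stopConfig("unknown contrast type: ", ct$type))
      nClamped <<- nClamped + (attr(rd, "nClamped") %||% 0L)
      fit <- samplePosterior(rd, nChains = inf$chains, nWarmup = inf$warmup,
                             nKept = inf$kept, seed = inf$seed)
      utils::write.csv(as.data.frame(drawsMatrix(fit)),
                       file.path(outDir, paste0("draws_", nm, ".csv")),
                       row.names = FALSE)
      fc <- foldChange(fit)
      groups <- lapply(levels(rd@group), function(lv)
        summarizeDraws(groupMeanDraws(fit, lv), label = lv))
      names(groups) <- levels(rd@group)
      list(fold = fc, groups = groups, rhatMax = max(splitRhat(fit), na.rm = TRUE),
           converged = isConverged(fit))
    })
    summaries[[nm]] <- res
  }
  log$responses_clamped <- nClamped
  log$convergence_warnings <-
    sum(!vapply(summaries, `[[`, logical(1), "converged"))

  report <- list(
    config = cfg,
    log = log,
    contrasts = lapply(summaries, function(s) {
      c(list(fold_change = list(median = postMedian(s$fold),
                                ci = unname(credInt(s$fold)),
                                fsr = fsr(s$fold)),
             rhat_max = s$rhatMax, converged = s$converged),
        list(group_means = lapply(s$groups, function(g)
          list(median = postMedian(g), ci = unname(credInt(g))))))
    })
  )
  jsonlite::write_json(report, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
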