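## End-to-end orchestration and the command-line interface.

#' Run the full pipeline on a dataset
#'
#' Classification, bout segmentation, per-population median bouts,
#' phase detection with metrics, daily/hourly attendance and the
#' summary tables, in one call. Deterministic for a fixed dataset and
#' parameters.
#'
#' @param dataset a `unicub_dataset`
#' @param extraction a [extraction_params()]
#' @param phase a [phase_params()]
#' @param truth optional truth ledger from [generate_dataset()] (used
#'   only to pass per-nest recording ends for censoring flags)
#' @return list: `states`, `bouts`, `median_bout_h` (per population),
#'   `phases`, `daily`, `hourly`, `species_summary`, `case_stats`
#' @export
run_pipeline <- function(dataset, extraction = extraction_params(),
                         phase = phase_params(), truth = NULL) {
  ds <- dataset
  states <- incubation_states(ds$temperature, ds$rfid, ds$tags,
                              ds$metadata, extraction)
  bouts <- segment_bouts(states, ds$rfid, ds$tags, extraction)
  md <- as.data.table(ds$metadata)
  ## per-population median bout, mapped per nest
  bt <- merge(bouts, md[, .(nest_id, population)], by = "nest_id")
  pop_med <- bt[, .(median_bout_h = population_median_bout(length_h)),
                by = population]
  mb_by_nest <- setNames(
    pop_med$median_bout_h[match(md$population, pop_med$population)],
    md$nest_id)
  mb_by_nest[is.na(mb_by_nest)] <- median(bouts$length_h)
  rec_end <- if (!is.null(truth))
    setNames(truth$nests$recording_end, truth$nests$nest_id) else NULL
  phases <- detect_uniparental_phases(bouts, mb_by_nest, md, ds$events,
                                      recording_end = rec_end,
                                      params = phase)
  inc0 <- setNames(md$incubation_start, md$nest_id)
  phases <- phase_metrics(phases, inc0, ds$references, md)
  daily <- attendance_records(states, phases, md, ds$references,
                              granularity = "daily")
  hourly <- attendance_records(states, phases, md, ds$references,
                               granularity = "hourly")
  list(states = states, bouts = bouts, median_bout_h = pop_med,
       phases = phases, daily = daily, hourly = hourly,
       species_summary = species_summary_table(ds, phases),
       case_stats = case_summary_stats(phases))
}

## build a sim_config from a flat config list, keeping defaults
.config_to_sim <- function(cfg) {
  known <- names(formals(sim_config))
  do.call(sim_config, cfg[intersect(names(cfg), known)])
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `extract`, `phases`, `attendance`, `fit`,
#' `report`, `run-all`. Options are `--config <file>` (flat
#' `key: value` or JSON), `--seed <int>`, `--in <dir>`, `--out <dir>`,
#' `--model <name>`. Emits interchange CSVs under `--out` and logs
#' per-stage record counts.
#'
#' @param args character vector (default `commandArgs(TRUE)`)
#' @return invisibly, the primary result of the subcommand
#' @export
unicub_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: unicub <simulate|extract|phases|attendance|fit|report|run-all> ",
            "[--config f] [--seed n] [--in dir] [--out dir] [--model m]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- list(out = ".", seed = 1L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else list()
  cfg$seed <- as.integer(opt$seed)
  log_n <- function(stage, n) message(sprintf("[unicub] %s: %d records", stage, n))

  load_in <- function() {
    dir <- opt[["in"]] %||% opt$out
    paths <- list(temperature = file.path(dir, "temperature.csv"),
                  rfid = file.path(dir, "rfid.csv"),
                  metadata = file.path(dir, "metadata.csv"),
                  events = file.path(dir, "events.csv"),
                  tags = file.path(dir, "tags.csv"),
                  references = file.path(dir, "references.csv"))
    paths <- paths[vapply(paths, file.exists, TRUE)]
    load_dataset(paths, validate = FALSE)
  }

  res <- switch(cmd,
    simulate = {
      sim <- generate_dataset(.config_to_sim(cfg))
      write_outputs(sim$dataset[c("temperature", "rfid", "metadata",
                                  "events", "tags")], opt$out)
      write_outputs(list(references = sim$dataset$references,
                         truth_bouts = sim$truth$bouts,
                         truth_nests = sim$truth$nests), opt$out)
      log_n("simulate/temperature", nrow(sim$dataset$temperature))
      sim
    },
    extract = {
      ds <- load_in()
      states <- incubation_states(ds$temperature, ds$rfid, ds$tags, ds$metadata)
      bouts <- segment_bouts(states, ds$rfid, ds$tags)
      write_outputs(list(states = states, bouts = bouts), opt$out)
      log_n("extract/bouts", nrow(bouts))
      list(states = states, bouts = bouts)
    },
    phases = ,
    attendance = ,
    `run-all` = {
      ds <- load_in()
      out <- run_pipeline(ds)
      write_outputs(out[c("states", "bouts", "phases", "daily", "hourly",
                          "species_summary", "case_stats")], opt$out)
      log_n("phases", nrow(out$phases))
      log_n("daily", nrow(out$daily)); log_n("hourly", nrow(out$hourly))
      out
    },
    fit = {
      dir <- opt[["in"]] %||% opt$out
      model <- opt$model %||% "daily"
      if (model == "success") {
        nt <- read_interchange(file.path(dir, "success_table.csv"))
        sm <- fit_success_model(nt, seed = cfg$seed)
        write_outputs(list(success_posterior = sm$posterior), opt$out)
        sm
      } else {
        rec <- read_interchange(file.path(dir,
          if (grepl("hourly", model)) "hourly.csv" else "daily.csv"))
        rec <- add_grouping_factors(rec)
        fit <- fit_mixed_model(rec, preset_model_spec(model))
        post <- posterior_summaries(fit, seed = cfg$seed)
        outs <- list(coefficients = post)
        if (fit$spec$family == "gaussian")
          outs$variance_shares <- variance_components(fit)
        write_outputs(outs, opt$out)
        log_n("fit/terms", nrow(post))
        list(fit = fit, posterior = post)
      }
    },
    report = {
      stats <- contingency_stats()
      tab <- data.table(target = names(stats), value = unname(stats))
      write_outputs(list(contingency = tab), opt$out)
      log_n("report", nrow(tab))
      tab
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
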