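# End-to-end orchestration: config in, report bundle out.
#
# Configs are plain lists (or YAML/JSON files with the same keys):
#   registry        path to the registry CSV            [required]
#   approvals       path to the approvals CSV           [optional]
#   snapshot_date   ISO date                            [required]
#   thresholds      three day counts (default 360/540/900)
#   group_key       drug-indication | drug-indication-sponsor
#   window_start    analysis window floor (default 2000-01-01)
#   out_dir         output directory                    [required]
#   years, window_years   for run_timeseries()

read_analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_pathpos(paste0("config file not found: ", config), "pathpos_config_error")
    }
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_pathpos("reading YAML configs requires the yaml package",
                     "pathpos_config_error")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  for (field in c("registry", "snapshot_date", "out_dir")) {
    if (is.null(config[[field]])) {
      stop_pathpos(paste0("config is missing the mandatory field: ", field),
                   "pathpos_config_error")
    }
  }
  config$thresholds <- config$thresholds %||% c(360L, 540L, 900L)
  config$group_key <- config$group_key %||% "drug-indication"
  config$window_start <- config$window_start %||% "2000-01-01"
  config
}

log_line <- function(con, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full estimation pipeline from a config
#'
#' Reads and filters the registry, repairs missing end dates, fits the POS
#' model, and writes the report bundle: `estimates.csv`, `counts.json`,
#' `filter_report.json`, `states.csv` and a structured `log.jsonl` with
#' per-stage record counts. Outputs are deterministic given identical
#' inputs (the log carries no timestamps). On any stage failure, partial
#' outputs are removed and the error names the stage.
#'
#' @param config a list or a YAML/JSON file path; see the field list above.
#' @return Invisibly, a list with the fit, the combined filter report and
#'   the output paths.
#' @export
run_estimate <- function(config) {
  cfg <- read_analysis_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(cfg$out_dir, c("estimates.csv", "counts.json",
                                      "filter_report.json", "states.csv",
                                      "log.jsonl"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)
  logcon <- file(outputs[5], open = "wt")
  on.exit(close(logcon), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pathpos(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "pathpos_stage_error")
    })
  }

  rd <- stage("read", read_registry(cfg$registry))
  log_line(logcon, "read", n_input = rd$report$n_input,
           n_output = rd$report$n_output)
  fl <- stage("filter", filter_records(rd$records, cfg$window_start))
  log_line(logcon, "filter", n_output = fl$report$n_output,
           n_pre_window = fl$report$n_dropped_pre_window)
  im <- stage("impute_end_dates", impute_end_dates(fl$records))
  log_line(logcon, "impute_end_dates",
           n_imputed = im$report$n_end_dates_imputed)
  report <- combine_reports(combine_reports(rd$report, fl$report), im$report)

  approvals <- if (!is.null(cfg$approvals)) {
    stage("approvals", read_approvals(cfg$approvals))
  } else NULL
  thresholds <- stage("thresholds",
                      pos_thresholds(cfg$snapshot_date, cfg$thresholds))
  fit <- stage("fit", pos_fit(im$records, approvals, thresholds = thresholds,
                              group_key = cfg$group_key))
  log_line(logcon, "fit", n_programs = nrow(fit$programs$programs),
           n_approvals = fit$counts$n_approval)

  stage("write", {
    utils::write.csv(pos_estimates_table(fit), outputs[1], row.names = FALSE)
    jsonlite::write_json(
      list(n = fit$counts$n, n_obs = fit$counts$n_obs, n_m = fit$counts$n_m,
           n_ip = fit$counts$n_ip, n_t = fit$counts$n_t,
           n_entry = fit$counts$n_entry, n_approval = fit$counts$n_approval),
      outputs[2], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(report)[1:5], outputs[3],
                         auto_unbox = TRUE, digits = NA)
    write_states(fit$states, outputs[4])
  })
  ok <- TRUE
  invisible(list(fit = fit, report = report, outputs = outputs))
}

#' Run the rolling-window time-series analysis from a config
#'
#' Fits the model as in [run_estimate()] and writes `timeseries.csv`: one
#' row per (year, measure) with the windowed phase-by-phase estimate, its
#' SE, the counts behind it and the boundary-bias flag for windows abutting
#' the snapshot.
#'
#' @param config as for [run_estimate()], plus `years` (integer vector;
#'   required) and optional `window_years` (default 3).
#' @return Invisibly, the time-series data.frame.
#' @export
run_timeseries <- function(config) {
  cfg <- read_analysis_config(config)
  if (is.null(cfg$years)) {
    stop_pathpos("config is missing the mandatory field: years",
                 "pathpos_config_error")
  }
  bundle <- run_estimate(cfg)
  series <- rolling_series(bundle$fit$states, years = as.integer(cfg$years),
                           window_years = as.integer(cfg$window_years %||% 3L))
  path <- file.path(cfg$out_dir, "timeseries.csv")
  utils::write.csv(series, path, row.names = FALSE)
  invisible(series)
}
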