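# Subgroup stratification, completion rates, durations, and rolling-window
# time series.

#' Per-phase trial completion rates
#'
#' The completion rate at Phase i is the proportion of concluded Phase i
#' trials tagged as completed; trials stopped early with positive results
#' count as completed, and ongoing/planned trials are excluded from the
#' denominator.
#'
#' @param records validated trial records.
#' @param by optional character vector of record columns to stratify by
#'   (e.g. `"therapeutic_group"`).
#' @return data.frame with `phase`, optional grouping columns,
#'   `n_concluded` and `rate` (`NA` when a cell has no concluded trials).
#' @export
completion_rates <- function(records, by = NULL) {
  records <- as_trial_records(records)
  dt <- as.data.table(records)
  dt[, phase := canonical_phase(phase_label)]
  dt <- dt[status %in% CONCLUDED_STATUSES]
  keys <- c("phase", by)
  out <- dt[, .(
    n_concluded = .N,
    rate = mean(status %in% c("completed", "terminated_positive"))
  ), by = keys]
  base <- if (is.null(by)) data.table(phase = 1:4) else
    as.data.table(merge(unique(as.data.frame(dt)[, by, drop = FALSE]),
                        data.frame(phase = 1:4)))
  out <- out[base, on = keys]
  out[is.na(n_concluded), n_concluded := 0L]
  setorderv(out, keys)
  as.data.frame(out)
}

#' Mean number of trials per development path, by phase
#'
#' @param programs a `dev_programs` object.
#' @return data.frame with `phase`, `n_paths` (paths with at least one
#'   observed trial in the phase) and `mean_trials`. Imputed (zero-trial)
#'   phases do not contribute.
#' @export
trials_per_path <- function(programs) {
  stopifnot(inherits(programs, "dev_programs"))
  rec <- programs$records
  per <- rec[, .(k = .N), by = .(pid, phase = cphase)]
  out <- per[, .(n_paths = .N, mean_trials = mean(k)), by = phase]
  setorder(out, phase)
  as.data.frame(out)
}

#' Median trial durations and clinic time
#'
#' Durations use concluded trials with observed (non-imputed) end dates,
#' measured in years of 365.25 days. Clinic time is the sum of the Phase
#' 1-3 medians: the typical time a successful program spends in trials.
#'
#' @param records validated trial records.
#' @param by optional stratification columns.
#' @return A list with `summary` (phase, group columns, `n`,
#'   `median_years`) and `clinic_time` (per group, the sum of the Phase 1-3
#'   medians).
#' @export
duration_stats <- function(records, by = NULL) {
  records <- as_trial_records(records)
  dt <- as.data.table(records)
  dt[, phase := canonical_phase(phase_label)]
  dt <- dt[status %in% CONCLUDED_STATUSES & !is.na(end_date) &
             !is.na(start_date) & !end_date_imputed]
  dt[, years := days_between(start_date, end_date) / DAYS_PER_YEAR]
  keys <- c("phase", by)
  summ <- dt[, .(n = .N, median_years = stats::median(years)), by = keys]
  setorderv(summ, keys)
  ct <- summ[phase <= 3L,
             .(clinic_time_years = sum(median_years), phases = .N), by = by]
  list(summary = as.data.frame(summ), clinic_time = as.data.frame(ct))
}

#' Duration gap between terminated and advanced programs
#'
#' Compares the median duration (in months of 30.4375 days) of Phase j
#' trials belonging to programs that advanced out of Phase j against those
#' that terminated there. A positive delta means trials in advanced
#' programs ran longer.
#'
#' @param states a `phase_states` object.
#' @param programs the `dev_programs` the states came from.
#' @param phase phase to compare, 1..3.
#' @param window optional `c(t1, t2)` restricting programs by their Phase j
#'   decisive date (used for 5-year rolling comparisons).
#' @return A list with the two medians, group sizes and
#'   `delta_months = advanced - terminated` (`NA` with counts when a group
#'   is empty).
#' @export
terminated_vs_advanced <- function(states, programs, phase,
                                   window = NULL) {
  stopifnot(inherits(states, "phase_states"),
            inherits(programs, "dev_programs"), phase %in% 1:3)
  ph <- as.integer(phase)
  st <- as.data.table(states)[phase == ph &
                                state %in% c("advanced", "terminated")]
  if (!is.null(window)) {
    t1 <- as.Date(window[1]); t2 <- as.Date(window[2])
    st <- st[!is.na(decisive_date) & decisive_date >= t1 & decisive_date <= t2]
  }
  rec <- programs$records[cphase == ph & status %in% CONCLUDED_STATUSES &
                            !is.na(end_date) & !is.na(start_date)]
  rec <- st[, .(pid, state)][rec, on = "pid", nomatch = NULL]
  rec[, months := days_between(start_date, end_date) / DAYS_PER_MONTH]
  med <- function(s) {
    v <- rec[state == s, months]
    list(n = length(v), median = if (length(v)) stats::median(v) else NA_real_)
  }
  a <- med("advanced"); t <- med("terminated")
  delta <- if (a$n > 0 && t$n > 0) a$median - t$median else NA_real_
  list(phase = phase, n_advanced = a$n, n_terminated = t$n,
       median_advanced_months = a$median, median_terminated_months = t$median,
       delta_months = delta)
}

#' Phase-wise biomarker stratification of transition counts
#'
#' Assigns each program's phase-j observation to the biomarker stratum if
#' and only if at least one trial in that phase carries the biomarker flag
#' (`selection_only`: patient-selection biomarkers; `expanded`: also trials
#' evaluating novel biomarkers). Because most biomarker programs do not use
#' biomarkers in every phase, estimates from these counts should use the
#' phase-by-phase estimators only. Trials observed before `date_floor` are
#' excluded so the strata cover comparable calendar time.
#'
#' @param records validated trial records.
#' @param approvals optional approvals table.
#' @param thresholds a [pos_thresholds].
#' @param mode `"selection_only"` or `"expanded"`.
#' @param date_floor drop trials whose observation date (end date, or start
#'   date while unconcluded) precedes this; `NULL` to keep everything.
#' @return A list with `with_biomarker` and `without_biomarker`
#'   `transition_counts` (imputed phases, carrying no trials, fall in the
#'   non-biomarker stratum). Per phase the two strata sum to the
#'   unstratified counts under the same floor.
#' @export
biomarker_counts <- function(records, approvals = NULL, thresholds,
                             mode = c("selection_only", "expanded"),
                             date_floor = as.Date("2005-01-01")) {
  mode <- match.arg(mode)
  records <- as_trial_records(records)
  if (!is.null(date_floor)) {
    obs_date <- ifelse(is.na(records$end_date), records$start_date,
                       records$end_date)
    records <- records[obs_date >= as.numeric(as.Date(date_floor)), ,
                       drop = FALSE]
  }
  programs <- build_programs(records, approvals)
  states <- classify_phase_states(programs, thresholds)
  flag <- if (mode == "selection_only") programs$records$biomarker_selection
  else programs$records$biomarker_selection | programs$records$biomarker_evaluation
  bio_phase <- unique(programs$records[flag %in% TRUE, .(pid, phase = cphase)])
  dt <- as.data.table(states)
  dt[, bio := FALSE]
  dt[bio_phase, on = c("pid", "phase"), bio := TRUE]
  approved_pids <- dt[phase == 4L & state == "approved", pid]
  stratum_counts <- function(want_bio) {
    core <- dt[phase <= 3L & bio == want_bio]
    tl <- function(ss) {
      v <- integer(3L)
      t0 <- core[state %in% ss, .N, by = phase]
      v[t0$phase] <- t0$N
      v
    }
    n_app <- core[phase == 3L & state %in% c("advanced", "missing_imputed") &
                    pid %in% approved_pids, .N]
    transition_counts(n = tl(OBSERVED_STATES), n_m = tl("missing_imputed"),
                      n_ip = tl("in_progress"), n_t = tl("terminated"),
                      n_approval = n_app, check = FALSE)
  }
  list(with_biomarker = stratum_counts(TRUE),
       without_biomarker = stratum_counts(FALSE),
       mode = mode, date_floor = date_floor)
}

#' Flag the lead indication of every drug
#'
#' The lead indication is the program whose earliest trial start date is
#' minimal among the drug's programs; ties break by earliest end date and
#' then lexicographic indication id, so exactly one program per drug is
#' flagged regardless of record order.
#'
#' @param programs a `dev_programs` object.
#' @return The same object with `is_lead_indication` set in
#'   `programs$programs`.
#' @export
lead_indications <- function(programs) {
  stopifnot(inherits(programs, "dev_programs"))
  pr <- copy(programs$programs)
  ord <- order(pr$drug_id,
               as.numeric(pr$first_start), as.numeric(pr$first_end),
               pr$indication_id, na.last = TRUE)
  pr <- pr[ord]
  pr[, is_lead_indication := seq_len(.N) == 1L, by = drug_id]
  setorder(pr, pid)
  programs$programs <- pr[]
  programs
}

#' POS conditioned on non-industry partners
#'
#' Splits programs into those with at least one non-industry partner and
#' those with none, computes path-by-path estimates in each stratum, and
#' reports the overall POS difference in percentage points.
#'
#' @param states a `phase_states` object.
#' @param programs the matching `dev_programs`.
#' @return A list with `with_partner`, `without_partner` (each `NULL` when
#'   its stratum is empty, otherwise overall path-by-path `pos_estimate`s
#'   plus counts) and `difference_pp`.
#' @export
partner_conditioning <- function(states, programs) {
  stopifnot(inherits(states, "phase_states"),
            inherits(programs, "dev_programs"))
  pr <- programs$programs
  stratum <- function(pids) {
    if (!length(pids)) return(NULL)
    counts <- tabulate_transitions(states, pids = pids)
    est <- tryCatch(pos_path_overall(counts),
                    pathpos_undefined_estimate = function(e) NULL)
    if (is.null(est)) return(NULL)
    list(overall = est, counts = counts)
  }
  w <- stratum(pr[max_partners >= 1L, pid])
  wo <- stratum(pr[max_partners == 0L, pid])
  diff_pp <- if (!is.null(w) && !is.null(wo)) {
    100 * (w$overall$value - wo$overall$value)
  } else NA_real_
  list(with_partner = w, without_partner = wo, difference_pp = diff_pp)
}

#' Rolling-window POS time series
#'
#' For each year `t` in `years`, computes windowed phase-by-phase estimates
#' over the window January 1 of `t - window_years + 1` through December 31
#' of `t`, with the final window clipped at the snapshot date. Estimates in
#' the window abutting the snapshot are flagged: too little time has
#' elapsed for terminations to be declared there, so those success rates
#' are biased upward (the boundary effect).
#'
#' @param states a `phase_states` object.
#' @param years integer vector of window end years.
#' @param window_years window length in calendar years (default 3).
#' @param pids optional program subset.
#' @return data.frame with one row per (year, measure): `year`, `measure`
#'   (`phase1_2`, `phase2_3`, `phase3_app`, `overall`), `value`, `se`,
#'   `numerator`, `denominator`, window bounds and `boundary_biased` flag.
#' @export
rolling_series <- function(states, years, window_years = 3L, pids = NULL) {
  stopifnot(inherits(states, "phase_states"))
  snapshot <- attr(states, "snapshot_date")
  rows <- lapply(years, function(t) {
    t1 <- as.Date(sprintf("%d-01-01", t - window_years + 1L))
    t2 <- min(as.Date(sprintf("%d-12-31", t)), snapshot)
    w <- pos_windowed(states, t1, t2, pids = pids)
    ests <- c(w$phase, list(w$overall))
    measure <- c("phase1_2", "phase2_3", "phase3_app", "overall")
    data.frame(
      year = t, measure = measure,
      value = vapply(ests, `[[`, numeric(1), "value"),
      se = vapply(ests, `[[`, numeric(1), "se"),
      numerator = vapply(ests, function(e) as.numeric(e$numerator), numeric(1)),
      denominator = vapply(ests, function(e) as.numeric(e$denominator),
                           numeric(1)),
      window_start = t1, window_end = t2,
      boundary_biased = t2 >= snapshot - 31L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "caveat") <- paste(
    "Estimates in windows abutting the snapshot date overestimate the true",
    "success rates: insufficient time has elapsed for terminations to be",
    "declared, shrinking the denominator.")
  out
}
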