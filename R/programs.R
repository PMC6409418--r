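# Grouping registry records into development programs and classifying the
# per-phase states that drive the transition tallies.
#
# A development program is all trials investigating one drug for one
# indication. Its per-phase state is one of: advanced (a higher phase or an
# approval is observed), terminated (enough time has elapsed since the last
# trial ended, or every trial failed), in_progress (censored at the
# snapshot), or missing_imputed (an interior phase with no records that the
# idealized Phase 1 -> 2 -> 3 process implies must have happened).

PHASE_STATES <- c("advanced", "terminated", "in_progress", "missing_imputed",
                  "approved")
OBSERVED_STATES <- c("advanced", "terminated", "in_progress")

#' Group trial records into development programs
#'
#' Assigns every record to exactly one program under the chosen grouping
#' key, deduplicates trials listed under multiple sponsors, joins the
#' approval table, and derives program-level attributes from the member
#' records. Optionally treats the presence of a Phase 4 (post-marketing)
#' trial as evidence of approval, dated at the earliest Phase 4 start.
#'
#' @param records validated trial records.
#' @param approvals optional data.frame (`drug_id`, `indication_id`,
#'   `approval_date`). Approvals with no matching records are retained as
#'   trial-less programs (with a warning) and excluded from transition
#'   counts.
#' @param group_key `"drug-indication"` (default; the POS is a property of a
#'   drug-indication development effort) or `"drug-indication-sponsor"`.
#' @param phase4_implies_approval logical; default `TRUE`.
#' @return An object of class `dev_programs`: a list with `programs` (one
#'   row per program with attributes), `records` (deduplicated member
#'   records keyed by program id `pid`) and the grouping metadata.
#' @export
build_programs <- function(records, approvals = NULL,
                           group_key = c("drug-indication",
                                         "drug-indication-sponsor"),
                           phase4_implies_approval = TRUE) {
  group_key <- match.arg(group_key)
  records <- as_trial_records(records)
  rec <- as.data.table(records)
  rec[, cphase := canonical_phase(phase_label)]
  keycols <- c("drug_id", "indication_id")
  if (group_key == "drug-indication-sponsor") keycols <- c(keycols, "sponsor_id")

  if (nrow(rec)) {
    setorderv(rec, c(keycols, "trial_id", "sponsor_id", "start_date"))
    rec[, pid := .GRP, by = keycols]
    rec <- unique(rec, by = c("pid", "trial_id"))
  } else {
    rec[, pid := integer()]
  }

  mode_chr <- function(x) {
    tab <- table(x)
    names(tab)[order(-tab, names(tab))][1L]
  }
  if (nrow(rec)) {
    programs <- rec[, .(
      drug_id = drug_id[1L],
      indication_id = indication_id[1L],
      sponsor_id = if (group_key == "drug-indication-sponsor") sponsor_id[1L] else NA_character_,
      therapeutic_group = mode_chr(therapeutic_group),
      orphan = any(orphan %in% TRUE),
      any_industry = any(sponsor_class == "industry"),
      industry_share = mean(sponsor_class == "industry"),
      max_partners = max(c(0L, n_nonindustry_partners), na.rm = TRUE),
      n_trials = .N,
      first_start = suppressWarnings(min(start_date, na.rm = TRUE)),
      first_end = suppressWarnings(min(end_date, na.rm = TRUE)),
      has_trials = any(cphase <= 3L)
    ), by = pid]
  } else {
    programs <- data.table(
      pid = integer(), drug_id = character(), indication_id = character(),
      sponsor_id = character(), therapeutic_group = character(),
      orphan = logical(), any_industry = logical(), industry_share = numeric(),
      max_partners = integer(), n_trials = integer(),
      first_start = as.Date(character()), first_end = as.Date(character()),
      has_trials = logical()
    )
  }
  programs[, first_start := as.Date(first_start, origin = "1970-01-01")]
  programs[, first_end := as.Date(first_end, origin = "1970-01-01")]
  programs[is.infinite(as.numeric(first_start)), first_start := as.Date(NA)]
  programs[is.infinite(as.numeric(first_end)), first_end := as.Date(NA)]
  programs[, approval_date := as.Date(NA)]

  if (!is.null(approvals) && nrow(approvals)) {
    app <- as.data.table(approvals)
    app[, approval_date := as.Date(approval_date)]
    programs[app, on = c("drug_id", "indication_id"),
             approval_date := i.approval_date]
    unmatched <- app[!programs[, .(drug_id, indication_id)],
                     on = c("drug_id", "indication_id")]
    if (nrow(unmatched)) {
      warning(sprintf(
        "%d approval(s) for unknown (drug, indication) pairs; retained as trial-less programs excluded from counts",
        nrow(unmatched)), call. = FALSE)
      extra <- data.table(
        pid = seq_len(nrow(unmatched)) + max(c(0L, programs$pid)),
        drug_id = unmatched$drug_id, indication_id = unmatched$indication_id,
        sponsor_id = NA_character_, therapeutic_group = NA_character_,
        orphan = FALSE, any_industry = FALSE, industry_share = NA_real_,
        max_partners = 0L, n_trials = 0L,
        first_start = as.Date(NA), first_end = as.Date(NA),
        has_trials = FALSE, approval_date = unmatched$approval_date
      )
      programs <- rbind(programs, extra)
    }
  }

  if (phase4_implies_approval && any(rec$cphase == 4L & !is.na(rec$start_date))) {
    p4 <- rec[cphase == 4L & !is.na(start_date),
              .(p4_start = min(start_date)), by = pid]
    if (nrow(p4)) {
      programs[p4, on = "pid",
               approval_date := fifelse(is.na(approval_date),
                                        as.Date(i.p4_start), approval_date)]
    }
  }

  structure(list(programs = programs[], records = rec[],
                 group_key = group_key,
                 phase4_implies_approval = phase4_implies_approval),
            class = "dev_programs")
}

#' @export
print.dev_programs <- function(x, ...) {
  cat(sprintf("Development programs: %d (%s key), %d records, %d approved\n",
              nrow(x$programs), x$group_key, nrow(x$records),
              sum(!is.na(x$programs$approval_date))))
  invisible(x)
}

#' Classify per-phase states of every development program
#'
#' Applies the elapsed-time termination heuristic at each program's highest
#' observed phase and labels every lower observed phase as advanced. With
#' `impute = TRUE` (the default) interior phases with no records between the
#' first observed phase and the highest evidence (observed phase or
#' approval) are marked `missing_imputed` via [impute_missing_phases()].
#' Approved programs get a terminal `approved` row (recorded as phase 4).
#'
#' Rules at the highest observed phase `j` of an unapproved program: if
#' every trial in the phase failed, the program is terminated regardless of
#' elapsed time; if any trial lacks an end date it is in progress; otherwise
#' it is terminated exactly when `snapshot - latest end date` strictly
#' exceeds the phase threshold, and in progress otherwise.
#'
#' @param programs a `dev_programs` object.
#' @param thresholds a [pos_thresholds] object.
#' @param impute mark interior missing phases (default `TRUE`).
#' @return An object of class `phase_states`: a `data.table` with one row
#'   per program-phase (`pid`, `drug_id`, `indication_id`, `phase`, `state`,
#'   `decisive_date`, `n_trials`), carrying the thresholds as attributes.
#' @export
classify_phase_states <- function(programs, thresholds, impute = TRUE) {
  stopifnot(inherits(programs, "dev_programs"),
            inherits(thresholds, "pos_thresholds"))
  rec <- programs$records
  snapshot <- thresholds$snapshot_date
  tdays <- thresholds$days

  concluded_ends <- rec[status %in% CONCLUDED_STATUSES & !is.na(end_date), end_date]
  if (length(concluded_ends) && all(concluded_ends > snapshot)) {
    stop_pathpos("snapshot_date is earlier than every trial end date",
                 "pathpos_config_error")
  }

  ph <- rec[cphase <= 3L, .(
    n_trials = .N,
    decisive_date = {
      d <- end_date[status %in% CONCLUDED_STATUSES & !is.na(end_date)]
      if (length(d)) max(d) else as.Date(NA)
    },
    any_open = any(is.na(end_date)),
    all_failed = all(status == "failed")
  ), by = .(pid, phase = cphase)]

  pr <- programs$programs[, .(pid, drug_id, indication_id, approval_date)]
  ph <- pr[ph, on = "pid"]
  ph[, approved := !is.na(approval_date)]
  ph[, max_obs := max(phase), by = pid]

  ph[, state := "advanced"]
  last <- ph$phase == ph$max_obs & !ph$approved
  elapsed <- days_between(ph$decisive_date, rep(snapshot, nrow(ph)))
  ph[last & all_failed, state := "terminated"]
  ph[last & !all_failed & any_open, state := "in_progress"]
  rest <- last & !ph$all_failed & !ph$any_open
  ph[rest, state := fifelse(elapsed[rest] > tdays[phase], "terminated",
                            "in_progress")]

  states <- ph[, .(pid, drug_id, indication_id, phase, state, decisive_date,
                   n_trials)]

  appr <- pr[!is.na(approval_date) & pid %in% states$pid,
             .(pid, drug_id, indication_id, phase = 4L, state = "approved",
               decisive_date = approval_date, n_trials = 0L)]
  states <- rbind(states, appr)
  setorder(states, pid, phase)

  out <- structure(states[], class = c("phase_states", class(states)))
  setattr(out, "snapshot_date", snapshot)
  setattr(out, "threshold_days", tdays)
  if (impute) out <- impute_missing_phases(out)
  out
}

#' Impute interior missing phases
#'
#' Under the idealized process every path passes through Phases 1, 2 and 3
#' in order, so an interior phase with no records between observed evidence
#' (an observed lower phase and either an observed higher phase or an
#' approval) must have happened; it is marked `missing_imputed` and counts
#' as a success. Phases below the first observed phase are never fabricated:
#' a path enters the analysis at its first observed phase. The operation is
#' idempotent.
#'
#' @param states a `phase_states` object from [classify_phase_states()].
#' @return The augmented `phase_states` object.
#' @export
impute_missing_phases <- function(states) {
  stopifnot(inherits(states, "phase_states"))
  snap <- attr(states, "snapshot_date")
  td <- attr(states, "threshold_days")
  dt <- as.data.table(states)
  span <- dt[, .(
    lo = min(c(phase[phase <= 3L], Inf)),
    hi_obs = max(c(phase[phase <= 3L], -Inf)),
    approved = any(state == "approved"),
    drug_id = drug_id[1L], indication_id = indication_id[1L]
  ), by = pid]
  span[, hi := fifelse(approved, 3, hi_obs)]
  span <- span[is.finite(lo) & hi > lo]
  if (nrow(span)) {
    gaps <- span[, .(phase = seq.int(lo, hi), drug_id = drug_id,
                     indication_id = indication_id), by = pid]
    gaps <- gaps[!dt[, .(pid, phase)], on = c("pid", "phase")]
    if (nrow(gaps)) {
      add <- gaps[, .(pid, drug_id, indication_id, phase = as.integer(phase),
                      state = "missing_imputed",
                      decisive_date = as.Date(NA), n_trials = 0L)]
      dt <- rbind(dt, add)
      setorder(dt, pid, phase)
    }
  }
  out <- structure(dt[], class = c("phase_states", class(dt)))
  setattr(out, "snapshot_date", snap)
  setattr(out, "threshold_days", td)
  out
}

#' @export
print.phase_states <- function(x, ...) {
  tab <- table(factor(x$state, levels = PHASE_STATES))
  cat(sprintf("Phase states for %d programs (snapshot %s)\n",
              length(unique(x$pid)), format(attr(x, "snapshot_date"))))
  print(tab)
  invisible(x)
}

#' Write the per-program state table
#' @param states a `phase_states` object.
#' @param path output CSV path.
#' @export
write_states <- function(states, path) {
  out <- as.data.frame(states)[, c("drug_id", "indication_id", "phase",
                                   "state", "decisive_date")]
  out$decisive_date <- ifelse(is.na(out$decisive_date), "",
                              format(out$decisive_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
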