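# Reading, validating, filtering and repairing flat trial-registry tables.
#
# One registry row is the quartet (trial, drug, indication, sponsor) plus the
# phase label, dates, status and subgroup flags. The on-disk format is plain
# CSV/TSV with ISO-8601 dates; the schema below is the package's canonical
# one (the commercial registries this mirrors do not publish a schema).

PHASE_LABELS <- c("P1", "P1_2", "P2", "P2_3", "P3", "P4")
TRIAL_STATUSES <- c("completed", "failed", "ongoing", "planned", "terminated_positive")
CONCLUDED_STATUSES <- c("completed", "failed", "terminated_positive")
SPONSOR_CLASSES <- c("industry", "non_industry")

REGISTRY_COLUMNS <- c(
  "trial_id", "drug_id", "indication_id", "sponsor_id", "sponsor_class",
  "phase_label", "start_date", "end_date", "status", "therapeutic_group",
  "biomarker_selection", "biomarker_evaluation", "orphan", "source_tag",
  "n_nonindustry_partners"
)

#' Construct a filter report
#'
#' Tallies of rows dropped, rejected or repaired by the registry IO layer.
#' The invariant `n_output = n_input - n_dropped_missing_dates_or_sponsor -
#' n_dropped_pre_window` holds for every report the package produces.
#'
#' @param n_input rows seen.
#' @param n_dropped_missing_dates_or_sponsor rows dropped for a missing
#'   start date, an unidentified sponsor, or an unparseable mandatory field.
#' @param n_dropped_pre_window rows dropped because they ended before the
#'   analysis window.
#' @param n_end_dates_imputed rows whose end date was filled in by
#'   [impute_end_dates()].
#' @param n_output rows surviving.
#' @param diagnostics character vector of row-numbered messages.
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(n_input = 0L, n_dropped_missing_dates_or_sponsor = 0L,
                          n_dropped_pre_window = 0L, n_end_dates_imputed = 0L,
                          n_output = 0L, diagnostics = character()) {
  rep <- list(
    n_input = as.integer(n_input),
    n_dropped_missing_dates_or_sponsor = as.integer(n_dropped_missing_dates_or_sponsor),
    n_dropped_pre_window = as.integer(n_dropped_pre_window),
    n_end_dates_imputed = as.integer(n_end_dates_imputed),
    n_output = as.integer(n_output),
    diagnostics = diagnostics
  )
  counts <- unlist(rep[1:5])
  if (any(counts < 0)) {
    stop_pathpos("filter report counts must be non-negative", "pathpos_report_error")
  }
  if (rep$n_output != rep$n_input - rep$n_dropped_missing_dates_or_sponsor -
        rep$n_dropped_pre_window) {
    stop_pathpos("filter report arithmetic violated: n_output != n_input - drops",
                 "pathpos_report_error")
  }
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Registry filter report\n")
  cat(sprintf("  rows in:                         %d\n", x$n_input))
  cat(sprintf("  dropped (missing date/sponsor):  %d\n", x$n_dropped_missing_dates_or_sponsor))
  cat(sprintf("  dropped (pre-window end):        %d\n", x$n_dropped_pre_window))
  cat(sprintf("  end dates imputed:               %d\n", x$n_end_dates_imputed))
  cat(sprintf("  rows out:                        %d\n", x$n_output))
  if (length(x$diagnostics)) {
    cat("  diagnostics:\n")
    for (d in utils::head(x$diagnostics, 10L)) cat("    - ", d, "\n", sep = "")
    if (length(x$diagnostics) > 10L) {
      cat(sprintf("    ... and %d more\n", length(x$diagnostics) - 10L))
    }
  }
  invisible(x)
}

# merge two reports produced by consecutive stages over the same stream
combine_reports <- function(a, b) {
  filter_report(
    n_input = a$n_input,
    n_dropped_missing_dates_or_sponsor =
      a$n_dropped_missing_dates_or_sponsor + b$n_dropped_missing_dates_or_sponsor,
    n_dropped_pre_window = a$n_dropped_pre_window + b$n_dropped_pre_window,
    n_end_dates_imputed = a$n_end_dates_imputed + b$n_end_dates_imputed,
    n_output = b$n_output,
    diagnostics = c(a$diagnostics, b$diagnostics)
  )
}

# Coerce and validate a data.frame of trial records. Used at every entry
# point so simulated and hand-built data pass through the same checks as
# data read from disk.
as_trial_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  missing_cols <- setdiff(missing_cols, "end_date_imputed")
  if (length(missing_cols)) {
    stop_pathpos(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "pathpos_schema_error")
  }
  if (!"end_date_imputed" %in% names(df)) df$end_date_imputed <- FALSE
  if (!inherits(df$start_date, "Date")) df$start_date <- parse_iso_date(df$start_date)
  if (!inherits(df$end_date, "Date")) df$end_date <- parse_iso_date(df$end_date)
  df$end_date_imputed <- as.logical(df$end_date_imputed)
  df$n_nonindustry_partners <- as.integer(df$n_nonindustry_partners)
  bad <- !is.na(df$end_date) & !is.na(df$start_date) & df$end_date < df$start_date
  if (any(bad)) {
    stop_pathpos(sprintf("end_date before start_date in %d record(s)", sum(bad)),
                 "pathpos_schema_error")
  }
  df
}

#' Read a trial registry table
#'
#' Reads a CSV/TSV registry export, validates every row against the canonical
#' schema, rejects rows with unparseable mandatory fields (with row-numbered
#' diagnostics) and optionally drops rows with a missing start date or an
#' unidentified sponsor.
#'
#' @param path path to a CSV (or TSV, by extension) file with the canonical
#'   header. Dates must be ISO 8601 (`YYYY-MM-DD`) or empty.
#' @param drop_incomplete drop rows whose start date is missing or whose
#'   sponsor is unidentified (empty `sponsor_id` or a `sponsor_class` outside
#'   `industry`/`non_industry`), tallying them in the report. If `FALSE`,
#'   such rows are rejected with a diagnostic instead.
#' @return A list with elements `records` (a validated data.frame, dates as
#'   `Date`, flags as logical) and `report` (a [filter_report]).
#' @seealso [filter_records()], [impute_end_dates()], [write_registry()]
#' @export
read_registry <- function(path, drop_incomplete = TRUE) {
  if (!file.exists(path)) {
    stop_pathpos(paste0("registry file not found: ", path), "pathpos_io_error")
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = '"',
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(REGISTRY_COLUMNS, "end_date_imputed"), names(raw))
  if (length(missing_cols)) {
    stop_pathpos(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "pathpos_schema_error")
  }
  if (!"end_date_imputed" %in% names(raw)) raw$end_date_imputed <- "false"
  n_input <- nrow(raw)
  diagnostics <- character()
  reject <- rep(FALSE, n_input)
  dropped_incomplete <- rep(FALSE, n_input)

  note <- function(rows, what) {
    if (length(rows)) {
      diagnostics <<- c(diagnostics, sprintf("row %d: %s", rows, what))
    }
  }

  # mandatory identifiers
  for (col in c("trial_id", "drug_id", "indication_id")) {
    bad <- which(trimws(raw[[col]]) == "")
    reject[bad] <- TRUE
    note(bad, paste0("empty ", col))
  }
  # enumerations
  bad <- which(!raw$phase_label %in% PHASE_LABELS)
  reject[bad] <- TRUE
  note(bad, sprintf("phase_label '%s' not one of %s",
                    raw$phase_label[bad], paste(PHASE_LABELS, collapse = "/")))
  bad <- which(!raw$status %in% TRIAL_STATUSES)
  reject[bad] <- TRUE
  note(bad, sprintf("status '%s' unrecognised", raw$status[bad]))

  # dates: empty is allowed (missing), non-empty must parse
  start <- parse_iso_date(raw$start_date)
  bad <- which(trimws(raw$start_date) != "" & is.na(start))
  reject[bad] <- TRUE
  note(bad, sprintf("start_date '%s' is not a valid ISO date", raw$start_date[bad]))
  end <- parse_iso_date(raw$end_date)
  bad <- which(trimws(raw$end_date) != "" & is.na(end))
  reject[bad] <- TRUE
  note(bad, sprintf("end_date '%s' is not a valid ISO date", raw$end_date[bad]))
  bad <- which(!is.na(start) & !is.na(end) & end < start)
  reject[bad] <- TRUE
  note(bad, "end_date precedes start_date")

  partners <- suppressWarnings(as.integer(raw$n_nonindustry_partners))
  bad <- which(is.na(partners) | partners < 0L)
  reject[bad] <- TRUE
  note(bad, "n_nonindustry_partners is not a non-negative integer")

  # unidentified sponsor / missing start date: dropped (flag) or rejected
  unidentified <- trimws(raw$sponsor_id) == "" |
    !raw$sponsor_class %in% SPONSOR_CLASSES
  incomplete <- (unidentified | is.na(start)) & !reject
  if (drop_incomplete) {
    dropped_incomplete[incomplete] <- TRUE
  } else {
    reject[incomplete] <- TRUE
    note(which(incomplete), "missing start date or unidentified sponsor")
  }

  keep <- !reject & !dropped_incomplete
  records <- data.frame(
    trial_id = raw$trial_id, drug_id = raw$drug_id,
    indication_id = raw$indication_id, sponsor_id = raw$sponsor_id,
    sponsor_class = raw$sponsor_class, phase_label = raw$phase_label,
    start_date = start, end_date = end,
    end_date_imputed = parse_logical(raw$end_date_imputed),
    status = raw$status, therapeutic_group = raw$therapeutic_group,
    biomarker_selection = parse_logical(raw$biomarker_selection),
    biomarker_evaluation = parse_logical(raw$biomarker_evaluation),
    orphan = parse_logical(raw$orphan), source_tag = raw$source_tag,
    n_nonindustry_partners = partners,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(records) <- NULL

  # duplicate quartets are a data error, not a droppable condition
  key <- do.call(paste, c(records[c("trial_id", "drug_id", "indication_id",
                                    "sponsor_id")], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(gsub("\r", " / ", key[dup]))
    stop_pathpos(paste0("duplicate (trial, drug, indication, sponsor) key(s): ",
                        paste(utils::head(offenders, 5L), collapse = "; ")),
                 "pathpos_duplicate_key_error")
  }

  report <- filter_report(
    n_input = n_input,
    n_dropped_missing_dates_or_sponsor = sum(reject) + sum(dropped_incomplete),
    n_output = nrow(records),
    diagnostics = diagnostics
  )
  list(records = records, report = report)
}

#' Filter registry records against the analysis window
#'
#' Removes records that ended before the analysis window opened, and
#' (optionally) records with a missing start date or unidentified sponsor.
#'
#' @param records validated records, as returned by [read_registry()] or
#'   [simulate_registry()].
#' @param window_start `Date` (or ISO string); records with
#'   `end_date < window_start` are dropped.
#' @param drop_unidentified drop records with missing `start_date` or empty
#'   `sponsor_id`.
#' @return A list with `records` and an additive `report`.
#' @export
filter_records <- function(records, window_start = as.Date("2000-01-01"),
                           drop_unidentified = TRUE) {
  records <- as_trial_records(records)
  if (is.character(window_start)) {
    ws <- parse_iso_date(window_start)
    if (is.na(ws)) {
      stop_pathpos(paste0("window_start is not a valid ISO date: ", window_start),
                   "pathpos_config_error")
    }
    window_start <- ws
  }
  n_input <- nrow(records)
  pre_window <- !is.na(records$end_date) & records$end_date < window_start
  incomplete <- rep(FALSE, n_input)
  if (drop_unidentified) {
    incomplete <- is.na(records$start_date) | trimws(records$sponsor_id) == "" |
      !records$sponsor_class %in% SPONSOR_CLASSES
  }
  incomplete <- incomplete & !pre_window
  keep <- !pre_window & !incomplete
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = filter_report(
    n_input = n_input,
    n_dropped_missing_dates_or_sponsor = sum(incomplete),
    n_dropped_pre_window = sum(pre_window),
    n_output = nrow(out)
  ))
}

#' Impute missing end dates by the median duration of similar trials
#'
#' Concluded trials (status `completed`, `failed` or `terminated_positive`)
#' that lack an end date receive `start_date + median duration` of donor
#' trials sharing the most specific available feature key. The fallback
#' chain is (canonical phase, therapeutic group, sponsor class) then
#' (canonical phase, therapeutic group), then (canonical phase), then all
#' donors. Donors are concluded trials with observed (non-imputed) end
#' dates; even-count medians average the two middle values and days are
#' rounded half-up. Trials with status `ongoing`/`planned` are censored, not
#' repaired, and keep their missing end dates.
#'
#' @param records validated records.
#' @return A list with `records` (repaired, `end_date_imputed` set) and
#'   `report` whose `n_end_dates_imputed` counts the repairs.
#' @export
impute_end_dates <- function(records) {
  records <- as_trial_records(records)
  cph <- canonical_phase(records$phase_label)
  concluded <- records$status %in% CONCLUDED_STATUSES
  need <- concluded & is.na(records$end_date) & !is.na(records$start_date)
  donor <- concluded & !is.na(records$end_date) & !is.na(records$start_date) &
    !records$end_date_imputed
  if (any(need) && !any(donor)) {
    stop_pathpos("no observed durations available to impute from",
                 "pathpos_imputation_error")
  }
  if (any(need)) {
    dur <- days_between(records$start_date[donor], records$end_date[donor])
    keys <- list(
      paste(cph[donor], records$therapeutic_group[donor],
            records$sponsor_class[donor], sep = "\r"),
      paste(cph[donor], records$therapeutic_group[donor], sep = "\r"),
      as.character(cph[donor])
    )
    med_by <- lapply(keys, function(k) tapply(dur, k, stats::median))
    med_global <- stats::median(dur)
    target_keys <- list(
      paste(cph[need], records$therapeutic_group[need],
            records$sponsor_class[need], sep = "\r"),
      paste(cph[need], records$therapeutic_group[need], sep = "\r"),
      as.character(cph[need])
    )
    fill <- rep(NA_real_, sum(need))
    for (level in 1:3) {
      m <- med_by[[level]][target_keys[[level]]]
      fill[is.na(fill) & !is.na(m)] <- m[is.na(fill) & !is.na(m)]
    }
    fill[is.na(fill)] <- med_global
    idx <- which(need)
    records$end_date[idx] <- records$start_date[idx] + round_half_up(fill)
    records$end_date_imputed[idx] <- TRUE
  }
  list(records = records, report = filter_report(
    n_input = nrow(records), n_output = nrow(records),
    n_end_dates_imputed = sum(need)
  ))
}

#' Write records back to the canonical CSV schema
#'
#' @param records validated records.
#' @param path output CSV path. The write round-trips losslessly through
#'   [read_registry()].
#' @export
write_registry <- function(records, path) {
  records <- as_trial_records(records)
  out <- records
  out$start_date <- ifelse(is.na(out$start_date), "",
                           format(out$start_date, "%Y-%m-%d"))
  out$end_date <- ifelse(is.na(out$end_date), "",
                         format(out$end_date, "%Y-%m-%d"))
  for (col in c("end_date_imputed", "biomarker_selection",
                "biomarker_evaluation", "orphan")) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a drug-indication approval table
#'
#' @param path CSV with columns `drug_id`, `indication_id`, `approval_date`
#'   (ISO 8601). The (drug, indication) pair must be unique.
#' @return data.frame with parsed approval dates.
#' @export
read_approvals <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("drug_id", "indication_id", "approval_date")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_pathpos(paste0("approvals table missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "pathpos_schema_error")
  }
  out <- data.frame(
    drug_id = raw$drug_id, indication_id = raw$indication_id,
    approval_date = parse_iso_date(raw$approval_date),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$approval_date)) {
    stop_pathpos("unparseable approval_date entries", "pathpos_schema_error")
  }
  if (anyDuplicated(out[c("drug_id", "indication_id")])) {
    stop_pathpos("duplicate (drug_id, indication_id) in approvals",
                 "pathpos_duplicate_key_error")
  }
  out
}

#' Write an approvals table
#' @param approvals data.frame with `drug_id`, `indication_id`, `approval_date`.
#' @param path output CSV path.
#' @export
write_approvals <- function(approvals, path) {
  out <- approvals
  out$approval_date <- format(as.Date(out$approval_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
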