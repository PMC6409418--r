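# Canonical phase mapping and threshold configuration.

#' Map registry phase labels to canonical phases
#'
#' Combined-phase trials are assigned to the later phase: Phase 1/2 trials
#' count as Phase 2 and Phase 2/3 trials as Phase 3, the standard convention
#' when tracing development paths.
#'
#' @param label character vector of phase labels (`P1`, `P1_2`, `P2`,
#'   `P2_3`, `P3`, `P4`).
#' @return integer vector of canonical phases in 1..4.
#' @examples
#' canonical_phase(c("P1", "P1_2", "P2_3", "P4"))
#' @export
canonical_phase <- function(label) {
  map <- c(P1 = 1L, P1_2 = 2L, P2 = 2L, P2_3 = 3L, P3 = 3L, P4 = 4L)
  out <- map[as.character(label)]
  if (anyNA(out)) {
    bad <- unique(as.character(label)[is.na(out)])
    stop_pathpos(paste0("unknown phase label(s): ", paste(bad, collapse = ", ")),
                 "pathpos_schema_error")
  }
  unname(out)
}

#' Termination-heuristic configuration
#'
#' A development program's latest observed phase is declared terminated when
#' the time elapsed between its most recent trial end date and the data
#' snapshot exceeds a per-phase threshold; otherwise it is still in
#' progress. The defaults (360, 540 and 900 days for Phases 1, 2 and 3)
#' allow for the typical gap before the next phase starts, with the Phase 3
#' threshold also covering regulatory submission and review.
#'
#' @param snapshot_date the date the registry snapshot was taken (right
#'   censoring point); `Date` or ISO string. Mandatory.
#' @param days positive integer vector of length 3: elapsed-day thresholds
#'   for Phases 1, 2, 3.
#' @return An object of class `pos_thresholds`.
#' @export
pos_thresholds <- function(snapshot_date, days = c(360L, 540L, 900L)) {
  if (missing(snapshot_date) || is.null(snapshot_date)) {
    stop_pathpos("snapshot_date is mandatory", "pathpos_config_error")
  }
  if (is.character(snapshot_date)) {
    sd <- parse_iso_date(snapshot_date)
    if (is.na(sd)) {
      stop_pathpos(paste0("snapshot_date is not a valid ISO date: ", snapshot_date),
                   "pathpos_config_error")
    }
    snapshot_date <- sd
  }
  days <- as.integer(days)
  if (length(days) != 3L || anyNA(days) || any(days <= 0L)) {
    stop_pathpos("thresholds must be three positive day counts",
                 "pathpos_config_error")
  }
  structure(list(days = days, snapshot_date = snapshot_date),
            class = "pos_thresholds")
}

#' @export
print.pos_thresholds <- function(x, ...) {
  cat(sprintf("Termination thresholds: %s days (Phases 1-3); snapshot %s\n",
              paste(x$days, collapse = "/"), format(x$snapshot_date)))
  invisible(x)
}
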