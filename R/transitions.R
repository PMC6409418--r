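# Transition counts: the n^j, n_m^j, n_ip^j, n_t^j, n^Approval tallies that
# feed every estimator, plus the path conservation law.
#
# Notation. n^j is the number of development paths with *observed* Phase j
# trials; n_m^j the number whose Phase j had to be imputed; the
# reconstructed total in Phase j is n^j + n_m^j. The conservation law for
# development paths,
#
#   n^{j+1}(total) = n^j(observed) + n_m^j - n_ip^j - n_t^j ,  j = 1, 2, 3
#
# (with the j = 3 left-hand side read as the number of approvals), says that
# every path present in a phase either advances, is still in progress, or
# terminated. Paths first observed at Phase >= 2 enter the bookkeeping at
# their first observed phase; the tally n_entry^j makes the identity exact
# in their presence and is zero whenever Phase 1 is always observed.

#' Construct a transition-counts object
#'
#' @param n integer length-3: paths with observed Phase j trials (the
#'   classical \eqn{n^j}).
#' @param n_m paths whose Phase j was imputed as missing.
#' @param n_ip paths all of whose Phase j trials are in progress at the
#'   snapshot.
#' @param n_t paths terminated in Phase j.
#' @param n_approval paths reaching approval.
#' @param n_entry paths entering the analysis at Phase j (first observed
#'   phase j); zero for data where Phase 1 is always recorded.
#' @param check validate non-negativity and bound invariants.
#' @return An object of class `transition_counts` with fields `n` (the
#'   reconstructed totals `n_obs + n_m`), `n_obs`, `n_m`, `n_ip`, `n_t`,
#'   `n_entry`, `n_approval`.
#' @export
transition_counts <- function(n, n_m = c(0L, 0L, 0L), n_ip = c(0L, 0L, 0L),
                              n_t = c(0L, 0L, 0L), n_approval = 0L,
                              n_entry = c(0L, 0L, 0L), check = TRUE) {
  as3 <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- rep(x, 3L)
    stopifnot(length(x) == 3L)
    x
  }
  obj <- structure(list(
    n_obs = as3(n), n_m = as3(n_m), n_ip = as3(n_ip), n_t = as3(n_t),
    n_entry = as3(n_entry), n_approval = as.integer(n_approval)
  ), class = "transition_counts")
  obj$n <- obj$n_obs + obj$n_m
  if (check) {
    all_counts <- c(obj$n_obs, obj$n_m, obj$n_ip, obj$n_t, obj$n_entry,
                    obj$n_approval)
    if (anyNA(all_counts) || any(all_counts < 0L)) {
      stop_pathpos("transition counts must be non-negative integers",
                   "pathpos_counts_error")
    }
    if (any(obj$n_ip + obj$n_t > obj$n)) {
      stop_pathpos("n_ip + n_t exceeds the path total in some phase",
                   "pathpos_counts_error")
    }
  }
  obj
}

#' @export
print.transition_counts <- function(x, ...) {
  m <- rbind(`paths (obs + imputed)` = x$n, observed = x$n_obs,
             imputed = x$n_m, in_progress = x$n_ip, terminated = x$n_t,
             entries = x$n_entry)
  colnames(m) <- paste("Phase", 1:3)
  print(m)
  cat("approvals:", x$n_approval, "\n")
  invisible(x)
}

#' Check the path conservation law
#'
#' Verifies, for j = 1, 2, 3, that the reconstructed path total in phase
#' j+1 (approvals for j = 3) equals
#' `n_obs[j] + n_m[j] - n_ip[j] - n_t[j] + n_entry[j+1]`.
#'
#' @param counts a `transition_counts` object.
#' @param strict error (rather than return `FALSE`) on violation.
#' @return `TRUE` invisibly if the law holds.
#' @export
check_conservation <- function(counts, strict = TRUE) {
  lhs <- c(counts$n[2], counts$n[3], counts$n_approval)
  rhs <- counts$n_obs + counts$n_m - counts$n_ip - counts$n_t +
    c(counts$n_entry[2], counts$n_entry[3], 0L)
  ok <- all(lhs == rhs)
  if (!ok && strict) {
    stop_pathpos(sprintf(
      "conservation law violated: phase totals (%s) vs flow (%s)",
      paste(lhs, collapse = ","), paste(rhs, collapse = ",")),
      "pathpos_conservation_error")
  }
  invisible(ok)
}

#' Tabulate phase transitions over classified programs
#'
#' Counts, for each phase j in 1..3, the development paths present
#' (observed or imputed), the imputed, in-progress and terminated paths,
#' and the approvals. The conservation law is asserted on the result;
#' programs with no Phase 1-3 trials (approval-only records) are excluded.
#'
#' @param states a `phase_states` object from [classify_phase_states()].
#' @param pids optional vector of program ids restricting the tabulation
#'   (used by subgroup analyses).
#' @return A `transition_counts` object.
#' @export
tabulate_transitions <- function(states, pids = NULL) {
  stopifnot(inherits(states, "phase_states"))
  dt <- as.data.table(states)
  if (!is.null(pids)) dt <- dt[pid %in% pids]
  core <- dt[phase <= 3L]
  tally <- function(cond) {
    v <- integer(3L)
    t0 <- core[cond(state), .N, by = phase]
    v[t0$phase] <- t0$N
    v
  }
  n_obs <- tally(function(s) s %in% OBSERVED_STATES)
  n_m <- tally(function(s) s == "missing_imputed")
  n_ip <- tally(function(s) s == "in_progress")
  n_t <- tally(function(s) s == "terminated")
  entry <- integer(3L)
  if (nrow(core)) {
    e0 <- core[, .(first = min(phase)), by = pid][, .N, by = first]
    entry[e0$first] <- e0$N
  }
  with_trials <- unique(core$pid)
  n_app <- length(intersect(dt[phase == 4L & state == "approved", pid],
                            with_trials))
  counts <- transition_counts(n = n_obs, n_m = n_m, n_ip = n_ip, n_t = n_t,
                              n_approval = n_app, n_entry = entry)
  check_conservation(counts, strict = TRUE)
  counts
}
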