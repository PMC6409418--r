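# Probability-of-success estimators.
#
# Path-by-path: ratios of reconstructed path totals, counting imputed
# (missing-record) phase passages in both numerator and denominator, with
# all-in-progress paths removed from the denominator:
#
#   POS_{j,j+1}      = n^{j+1}_tot / (n^j + n_m^j - n_ip^j)
#   POS_{1,APP}      = n^APP / (n^1 + n_m^1 - n_ip^1 - n_ip^2 - n_ip^3)
#
# Phase-by-phase (the classical approach): directly observed transitions
# over directly observed programs, multiplied across phases:
#
#   POS^p_{j,j+1}    = (n^{j+1}_tot - n_m^j) / (n^j - n_ip^j)
#   POS^p_{1,APP}    = prod_j POS^p_{j,j+1}
#
# where n^j is the observed path count and n^j_tot = n^j + n_m^j. The two
# coincide exactly when nothing is imputed and nothing is censored; under
# interior missingness the path-by-path overall estimate stays unbiased
# while the phase-by-phase product is pulled down.

phase_total <- function(counts, j) {
  if (j <= 3L) counts$n[j] else counts$n_approval
}

undefined_estimate <- function(what, counts) {
  stop(structure(
    class = c("pathpos_undefined_estimate", "pathpos_error", "error",
              "condition"),
    list(message = paste0("undefined estimate: ", what,
                          " has a non-positive denominator"),
         call = sys.call(-1), counts = counts)
  ))
}

new_pos_estimate <- function(value, numerator, denominator, method,
                             phase_from, phase_to) {
  # short-window estimates can leave [0, 1] (numerator and denominator count
  # different programs); the binomial SE is meaningless there
  se <- if (is.finite(value) && value >= 0 && value <= 1) {
    binomial_se(value, denominator)
  } else NA_real_
  structure(list(
    value = value, numerator = numerator, denominator = denominator,
    se = se, method = method,
    phase_from = phase_from, phase_to = phase_to
  ), class = "pos_estimate")
}

#' @export
print.pos_estimate <- function(x, ...) {
  cat(sprintf("POS %s -> %s (%s): %.3f (SE %.4f) [%d / %d]\n",
              as.character(x$phase_from), as.character(x$phase_to),
              gsub("_", "-", x$method), x$value, x$se,
              x$numerator, x$denominator))
  invisible(x)
}

#' @export
as.data.frame.pos_estimate <- function(x, ...) {
  data.frame(method = x$method, phase_from = as.character(x$phase_from),
             phase_to = as.character(x$phase_to), value = x$value,
             se = x$se, numerator = x$numerator,
             denominator = x$denominator, stringsAsFactors = FALSE)
}

#' Binomial standard error of a proportion
#'
#' `sqrt(p (1 - p) / n)` with `n` the estimator's own denominator; the
#' convention used for every standard error this package reports.
#'
#' @param value the proportion.
#' @param denominator the count it was computed over (must be positive).
#' @return the standard error, on the same scale as `value`.
#' @examples
#' binomial_se(0.5, 25)  # 0.1
#' @export
binomial_se <- function(value, denominator) {
  stopifnot(all(denominator > 0))
  sqrt(value * (1 - value) / denominator)
}

#' Path-by-path POS for one phase transition
#'
#' The ratio of development paths in Phase j+1 (observed and imputed) to
#' paths in Phase j (observed and imputed, minus those entirely in
#' progress). For j = 3 the numerator is the approval count.
#'
#' @param counts a `transition_counts` object.
#' @param j phase, 1..3.
#' @return A `pos_estimate`.
#' @export
pos_path <- function(counts, j) {
  stopifnot(inherits(counts, "transition_counts"), j %in% 1:3)
  den <- counts$n[j] - counts$n_ip[j]
  if (den <= 0) undefined_estimate(sprintf("POS_%d,%d (path-by-path)", j, j + 1L), counts)
  num <- phase_total(counts, j + 1L)
  new_pos_estimate(num / den, num, den, "path_by_path", j,
                   if (j == 3L) "approval" else j + 1L)
}

#' Path-by-path overall POS (Phase 1 to approval)
#'
#' The proportion of development paths entering Phase 1 that reach
#' approval, with paths still in progress at any phase removed from the
#' denominator.
#'
#' @param counts a `transition_counts` object.
#' @return A `pos_estimate`.
#' @export
pos_path_overall <- function(counts) {
  pos_to_approval(counts, 1L)
}

#' Path-by-path POS from Phase i to approval
#'
#' @param counts a `transition_counts` object.
#' @param i starting phase, 1..3. `i = 1` is the overall POS (likelihood of
#'   approval).
#' @return A `pos_estimate`.
#' @export
pos_to_approval <- function(counts, i) {
  stopifnot(inherits(counts, "transition_counts"), i %in% 1:3)
  den <- counts$n[i] - sum(counts$n_ip[i:3])
  if (den <= 0) undefined_estimate(sprintf("POS_%d,APP (path-by-path)", i), counts)
  new_pos_estimate(counts$n_approval / den, counts$n_approval, den,
                   "path_by_path", i, "approval")
}

#' Phase-by-phase POS for one phase transition
#'
#' The classical estimator: directly observed phase transitions over
#' directly observed programs in the phase (minus those entirely in
#' progress).
#'
#' @param counts a `transition_counts` object.
#' @param j phase, 1..3.
#' @return A `pos_estimate`.
#' @export
pos_phase <- function(counts, j) {
  stopifnot(inherits(counts, "transition_counts"), j %in% 1:3)
  den <- counts$n_obs[j] - counts$n_ip[j]
  if (den <= 0) undefined_estimate(sprintf("POS^p_%d,%d (phase-by-phase)", j, j + 1L), counts)
  num <- phase_total(counts, j + 1L) - counts$n_m[j]
  new_pos_estimate(num / den, num, den, "phase_by_phase", j,
                   if (j == 3L) "approval" else j + 1L)
}

#' Phase-by-phase overall POS
#'
#' The product of the three per-phase estimates; its standard error is the
#' first-order delta-method value treating the factors as independent.
#'
#' @param counts a `transition_counts` object.
#' @return A `pos_estimate` (the `se` field uses the delta method, the
#'   `denominator` is the Phase 1 denominator).
#' @export
pos_phase_overall <- function(counts) {
  ests <- lapply(1:3, function(j) {
    tryCatch(pos_phase(counts, j), pathpos_undefined_estimate = function(e) {
      stop_pathpos(sprintf("overall phase-by-phase POS undefined: Phase %d factor has no observed denominator", j),
                   "pathpos_undefined_estimate")
    })
  })
  p <- vapply(ests, `[[`, numeric(1), "value")
  se <- vapply(ests, `[[`, numeric(1), "se")
  value <- prod(p)
  grad <- vapply(1:3, function(j) prod(p[-j]), numeric(1))
  out <- structure(list(
    value = value, numerator = NA_integer_,
    denominator = ests[[1]]$denominator,
    se = sqrt(sum((grad * se)^2)), method = "phase_by_phase",
    phase_from = 1L, phase_to = "approval", factors = ests
  ), class = "pos_estimate")
  out
}

#' Windowed phase-by-phase POS
#'
#' Restricts the transition tallies to phase observations whose decisive
#' date (the latest end date among the phase's concluded trials) falls in
#' `[t1, t2]`, then applies the phase-by-phase estimators. Imputed phases
#' carry no dates and never enter a window; approvals are dated by the
#' program's observed Phase 3 decisive date. Phases with no in-window
#' membership yield `NA` estimates rather than errors, so rolling series
#' stay rectangular.
#'
#' @param states a `phase_states` object.
#' @param t1,t2 window bounds (`Date` or ISO strings), `t1 <= t2`.
#' @param pids optional program-id subset.
#' @return A list with `phase` (list of three `pos_estimate`s, possibly
#'   `NA`-valued), `overall`, `counts` and the window bounds.
#' @export
pos_windowed <- function(states, t1, t2, pids = NULL) {
  stopifnot(inherits(states, "phase_states"))
  if (is.character(t1)) t1 <- parse_iso_date(t1)
  if (is.character(t2)) t2 <- parse_iso_date(t2)
  if (is.na(t1) || is.na(t2) || t1 > t2) {
    stop_pathpos("window bounds must be valid dates with t1 <= t2",
                 "pathpos_config_error")
  }
  dt <- as.data.table(states)
  if (!is.null(pids)) dt <- dt[pid %in% pids]
  approved_pids <- dt[phase == 4L & state == "approved", pid]
  w <- dt[phase <= 3L & state %in% OBSERVED_STATES & !is.na(decisive_date) &
            decisive_date >= t1 & decisive_date <= t2]
  tally <- function(sel) {
    v <- integer(3L)
    t0 <- w[sel, .N, by = phase]
    v[t0$phase] <- t0$N
    v
  }
  n_obs <- tally(w$state %in% OBSERVED_STATES)
  n_ip <- tally(w$state == "in_progress")
  n_t <- tally(w$state == "terminated")
  n_app <- w[phase == 3L & state == "advanced" & pid %in% approved_pids, .N]
  counts <- transition_counts(n = n_obs, n_ip = n_ip, n_t = n_t,
                              n_approval = n_app, check = FALSE)
  na_est <- function(j) structure(list(
    value = NA_real_, numerator = NA_integer_, denominator = NA_integer_,
    se = NA_real_, method = "phase_by_phase", phase_from = j,
    phase_to = if (j == 3L) "approval" else j + 1L
  ), class = "pos_estimate")
  phase_ests <- lapply(1:3, function(j) {
    tryCatch(pos_phase(counts, j),
             pathpos_undefined_estimate = function(e) na_est(j))
  })
  p <- vapply(phase_ests, `[[`, numeric(1), "value")
  se <- vapply(phase_ests, `[[`, numeric(1), "se")
  overall <- if (anyNA(p)) {
    o <- na_est(1L)
    o$phase_to <- "approval"
    o
  } else {
    grad <- vapply(1:3, function(j) prod(p[-j]), numeric(1))
    structure(list(value = prod(p), numerator = NA_integer_,
                   denominator = phase_ests[[1]]$denominator,
                   se = sqrt(sum((grad * se)^2)), method = "phase_by_phase",
                   phase_from = 1L, phase_to = "approval"),
              class = "pos_estimate")
  }
  list(phase = phase_ests, overall = overall, counts = counts,
       t1 = t1, t2 = t2)
}
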