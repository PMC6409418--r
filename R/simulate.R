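# Synthetic trial-registry generator with known ground truth.
#
# Each drug carries one or more indications; each (drug, indication)
# program advances through Phases 1-3 by independent Bernoulli draws with
# per-phase probabilities theta (optionally modified by biomarker and
# partner effects), runs one or more trials per attempted phase with
# lognormal durations, and is right-censored at a snapshot date. Advancing
# programs can lose their entire Phase 2 record set with probability m --
# exactly the missingness pattern on which the path-by-path and
# phase-by-phase estimators disagree.

#' Generator configuration
#'
#' Defaults describe a registry resembling industry-wide drug development
#' over 2000-2015: per-phase advancement probabilities (0.65, 0.55, 0.60),
#' trials-per-phase means (1.7, 2.0, 2.8, 3.2), median trial durations of
#' 1.6, 2.9 and 3.8 years for Phases 1-3, completion rates of 91.4%, 81.1%,
#' 84.9% and 87.2%, terminated Phase 2 trials concluding 8.1 months earlier
#' (and terminated Phase 3 trials 3.2 months later) than advanced ones, and
#' a snapshot on 2015-10-31.
#'
#' @param n_drugs number of drugs.
#' @param indication_geom_p geometric parameter for extra indications per
#'   drug (expected indications `1 + (1-p)/p`, truncated at
#'   `max_indications`).
#' @param max_indications cap on indications per drug.
#' @param theta true advancement probabilities for Phases 1-3.
#' @param trials_lambda Poisson means for extra trials per phase (phases
#'   1-4); each attempted phase has `1 + Poisson(lambda)` trials.
#' @param duration_median_days median trial duration per phase (days).
#' @param duration_sdlog lognormal dispersion of durations.
#' @param trial_start_spread_days trials within a phase start uniformly
#'   within this many days of the phase opening.
#' @param inter_phase_gap_days uniform range of the gap between a phase's
#'   last trial end and the next phase's first trial start.
#' @param approval_gap_days uniform range from Phase 3 end to approval.
#' @param snapshot_date right-censoring date; trials ending after it are
#'   emitted as `ongoing` without end dates, trials starting after it are
#'   invisible.
#' @param program_start_window uniform range of Phase 1 opening dates.
#' @param missingness_m probability that an advancing program (one that
#'   progressed past Phase 2) loses every Phase 2 record.
#' @param biomarker_fraction,biomarker_effect fraction of programs using
#'   patient-selection biomarkers and the multiplier they apply to theta.
#' @param orphan_fraction fraction of programs with orphan indications.
#' @param industry_fraction fraction of programs with an industry sponsor.
#' @param partner_fraction,partner_effect fraction of programs with
#'   non-industry partners and the per-phase multiplier on theta.
#' @param completion_rates per-phase probability that a concluded trial is
#'   tagged completed rather than failed.
#' @param terminated_positive_rate probability that a completed trial is
#'   recorded as stopped early with positive results.
#' @param duration_gap_terminated_months per-phase amount by which trials
#'   in phases the program terminated in run shorter (positive) or longer
#'   (negative) than trials in advanced phases.
#' @param duplicate_fraction fraction of rows re-emitted under a
#'   co-sponsor, mimicking one trial appearing as several registry rows.
#' @param combined_label_rate fraction of Phase 2/3 trials emitted under
#'   the combined labels `P1_2` / `P2_3`.
#' @param therapeutic_groups,group_weights categories and sampling weights.
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(
    n_drugs = 500L,
    indication_geom_p = 0.7,
    max_indications = 6L,
    theta = c(0.65, 0.55, 0.60),
    trials_lambda = c(0.7, 1.0, 1.8, 2.2),
    duration_median_days = c(584, 1059, 1388, 730),
    duration_sdlog = 0.5,
    trial_start_spread_days = 180,
    inter_phase_gap_days = c(60, 360),
    approval_gap_days = c(180, 540),
    snapshot_date = "2015-10-31",
    program_start_window = c("2000-01-01", "2012-12-31"),
    missingness_m = 0,
    biomarker_fraction = 0.06,
    biomarker_effect = 1.25,
    orphan_fraction = 0.08,
    industry_fraction = 0.35,
    partner_fraction = 0.30,
    partner_effect = 1.15,
    completion_rates = c(0.914, 0.811, 0.849, 0.872),
    terminated_positive_rate = 0.02,
    duration_gap_terminated_months = c(0, 8.1, -3.2),
    duplicate_fraction = 0.03,
    combined_label_rate = 0.05,
    therapeutic_groups = c("oncology", "cns", "cardiovascular",
                           "infectious_disease", "metabolic", "autoimmune"),
    group_weights = c(0.30, 0.15, 0.12, 0.18, 0.13, 0.12)) {
  cfg <- as.list(environment())
  cfg$n_drugs <- as.integer(n_drugs)
  cfg$snapshot_date <- if (is.character(snapshot_date))
    parse_iso_date(snapshot_date) else as.Date(snapshot_date)
  cfg$program_start_window <- if (is.character(program_start_window))
    parse_iso_date(program_start_window) else as.Date(program_start_window)
  probs <- c(cfg$theta, indication_geom_p, missingness_m, biomarker_fraction,
             orphan_fraction, industry_fraction, partner_fraction,
             cfg$completion_rates, terminated_positive_rate,
             duplicate_fraction, combined_label_rate)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop_pathpos("all probabilities must lie in [0, 1]", "pathpos_config_error")
  }
  max_mult <- max(1, biomarker_effect) * max(1, partner_effect)
  if (any(cfg$theta * max_mult > 1)) {
    stop_pathpos("infeasible config: subgroup effects push an advancement probability above 1",
                 "pathpos_config_error")
  }
  if (length(cfg$theta) != 3L || length(cfg$trials_lambda) != 4L ||
      length(cfg$duration_median_days) != 4L ||
      length(cfg$completion_rates) != 4L ||
      length(cfg$duration_gap_terminated_months) != 3L) {
    stop_pathpos("theta has length 3; per-phase vectors have length 4 (3 for the duration gap)",
                 "pathpos_config_error")
  }
  if (any(cfg$duration_median_days <= 0) || cfg$duration_sdlog <= 0 ||
      cfg$n_drugs < 1L) {
    stop_pathpos("distribution parameters must be positive", "pathpos_config_error")
  }
  if (anyNA(cfg$snapshot_date) || anyNA(cfg$program_start_window)) {
    stop_pathpos("snapshot_date and program_start_window must be valid dates",
                 "pathpos_config_error")
  }
  structure(cfg, class = "registry_config")
}

runif_range <- function(n, range) range[1] + stats::runif(n) * (range[2] - range[1])

#' Generate a synthetic trial registry
#'
#' Deterministic given `(config, seed)`: identical inputs give identical
#' outputs. The emitted records use the canonical registry schema, so
#' generated data exercises the same readers and pipeline as real data.
#'
#' @param config a [registry_config].
#' @param seed integer seed for the single pseudo-random stream.
#' @return An object of class `registry_sim`: a list with `records` (trial
#'   rows), `approvals`, `truth` (one row of latent outcomes per program)
#'   and the `config` echo.
#' @seealso [truth_summary()] for exact latent counts.
#' @export
simulate_registry <- function(config = registry_config(), seed = 1L) {
  stopifnot(inherits(config, "registry_config"))
  set.seed(as.integer(seed))
  cfg <- config

  n_ind <- 1L + pmin(stats::rgeom(cfg$n_drugs, cfg$indication_geom_p),
                     cfg$max_indications - 1L)
  drug_idx <- rep(seq_len(cfg$n_drugs), n_ind)
  ind_idx <- sequence(n_ind)
  P <- length(drug_idx)
  drug_id <- sprintf("DRG%05d", drug_idx)
  indication_id <- sprintf("IND%02d", ind_idx)

  tg <- sample(cfg$therapeutic_groups, P, replace = TRUE,
               prob = cfg$group_weights)
  orphan <- stats::runif(P) < cfg$orphan_fraction
  biomarker <- stats::runif(P) < cfg$biomarker_fraction
  industry <- stats::runif(P) < cfg$industry_fraction
  partnered <- stats::runif(P) < cfg$partner_fraction
  partners <- ifelse(partnered, 1L + stats::rpois(P, 0.4), 0L)
  sponsor_id <- ifelse(industry,
                       sprintf("SPI%03d", 1L + (drug_idx %% 97L)),
                       sprintf("SPN%03d", 1L + (drug_idx %% 61L)))

  mult <- ifelse(biomarker, cfg$biomarker_effect, 1) *
    ifelse(partnered, cfg$partner_effect, 1)
  theta_eff <- outer(mult, cfg$theta)  # P x 3
  adv <- matrix(stats::runif(3L * P), P, 3L) < theta_eff
  attempted <- cbind(TRUE, adv[, 1L], adv[, 1L] & adv[, 2L])
  approved_latent <- adv[, 1L] & adv[, 2L] & adv[, 3L]

  phase_start <- as.numeric(runif_range(P, cfg$program_start_window))
  snapshot <- as.numeric(cfg$snapshot_date)

  trial_rows <- vector("list", 5L)
  phase_end <- rep(NA_real_, P)
  for (j in 1:3) {
    act <- which(attempted[, j])
    if (!length(act)) next
    k <- 1L + stats::rpois(length(act), cfg$trials_lambda[j])
    pid_t <- rep(act, k)
    t_start <- phase_start[pid_t] +
      stats::runif(length(pid_t), 0, cfg$trial_start_spread_days)
    dur <- stats::rlnorm(length(pid_t), log(cfg$duration_median_days[j]),
                         cfg$duration_sdlog)
    terminated_here <- attempted[pid_t, j] & !adv[pid_t, j]
    gap_days <- cfg$duration_gap_terminated_months[j] * DAYS_PER_MONTH
    dur[terminated_here] <- pmax(30, dur[terminated_here] - gap_days)
    t_end <- t_start + round(dur)
    completed <- stats::runif(length(pid_t)) < cfg$completion_rates[j]
    first_of_program <- !duplicated(pid_t)
    completed[first_of_program & adv[pid_t, j]] <- TRUE
    status <- ifelse(completed, "completed", "failed")
    tpos <- completed & stats::runif(length(pid_t)) < cfg$terminated_positive_rate
    status[tpos] <- "terminated_positive"
    trial_rows[[j]] <- data.table(pid = pid_t, phase = j, start = t_start,
                                  end = t_end, status = status)
    pe <- tapply(t_end, pid_t, max)
    phase_end[as.integer(names(pe))] <- pe
    nxt <- phase_end[act] + runif_range(length(act), cfg$inter_phase_gap_days)
    phase_start[act] <- nxt
  }

  approval_date <- rep(NA_real_, P)
  ap <- which(approved_latent)
  if (length(ap)) {
    approval_date[ap] <- phase_end[ap] +
      runif_range(length(ap), cfg$approval_gap_days)
  }
  approved_obs <- approved_latent & !is.na(approval_date) &
    approval_date <= snapshot

  a4 <- which(approved_obs)
  if (length(a4)) {
    k4 <- 1L + stats::rpois(length(a4), cfg$trials_lambda[4])
    pid_t <- rep(a4, k4)
    t_start <- approval_date[pid_t] + stats::runif(length(pid_t), 30, 360)
    dur <- stats::rlnorm(length(pid_t), log(cfg$duration_median_days[4]),
                         cfg$duration_sdlog)
    t_end <- t_start + round(dur)
    completed <- stats::runif(length(pid_t)) < cfg$completion_rates[4]
    status <- ifelse(completed, "completed", "failed")
    trial_rows[[4L]] <- data.table(pid = pid_t, phase = 4L, start = t_start,
                                   end = t_end, status = status)
  }

  trials <- rbindlist(trial_rows[!vapply(trial_rows, is.null, logical(1))])
  trials <- trials[start <= snapshot]
  trials[, ongoing := end > snapshot]
  trials[ongoing == TRUE, `:=`(status = "ongoing", end = NA_real_)]

  # interior missingness: advancing programs lose their Phase 2 record set
  advancing <- adv[, 1L] & adv[, 2L]
  deleted <- advancing & stats::runif(P) < cfg$missingness_m
  trials <- trials[!(phase == 2L & deleted[pid])]

  setorder(trials, pid, phase, start)
  trials[, trial_id := sprintf("TRL%07d", .I)]

  label <- c("P1", "P2", "P3", "P4")[trials$phase]
  if (cfg$combined_label_rate > 0 && nrow(trials)) {
    flip <- stats::runif(nrow(trials)) < cfg$combined_label_rate
    label[flip & trials$phase == 2L] <- "P1_2"
    label[flip & trials$phase == 3L] <- "P2_3"
  }

  records <- data.frame(
    trial_id = trials$trial_id,
    drug_id = drug_id[trials$pid],
    indication_id = indication_id[trials$pid],
    sponsor_id = sponsor_id[trials$pid],
    sponsor_class = ifelse(industry[trials$pid], "industry", "non_industry"),
    phase_label = label,
    start_date = as.Date(round(trials$start), origin = "1970-01-01"),
    end_date = as.Date(round(trials$end), origin = "1970-01-01"),
    end_date_imputed = FALSE,
    status = trials$status,
    therapeutic_group = tg[trials$pid],
    biomarker_selection = biomarker[trials$pid],
    biomarker_evaluation = biomarker[trials$pid] |
      (stats::runif(nrow(trials)) < 0.03),
    orphan = orphan[trials$pid],
    source_tag = sample(c("ctgov", "press", "analyst"), nrow(trials),
                        replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    n_nonindustry_partners = partners[trials$pid],
    stringsAsFactors = FALSE
  )

  if (cfg$duplicate_fraction > 0 && nrow(records)) {
    ndup <- floor(cfg$duplicate_fraction * nrow(records))
    if (ndup > 0) {
      idx <- sample.int(nrow(records), ndup)
      dup <- records[idx, , drop = FALSE]
      dup$sponsor_id <- sprintf("SPC%02d", 1L + (idx %% 23L))
      dup$sponsor_class <- "non_industry"
      records <- rbind(records, dup)
    }
  }
  rownames(records) <- NULL

  approvals <- data.frame(
    drug_id = drug_id[approved_obs],
    indication_id = indication_id[approved_obs],
    approval_date = as.Date(round(approval_date[approved_obs]),
                            origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    pid = seq_len(P), drug_id = drug_id, indication_id = indication_id,
    therapeutic_group = tg, orphan = orphan, biomarker = biomarker,
    industry = industry, partners = partners,
    theta1 = theta_eff[, 1L], theta2 = theta_eff[, 2L],
    theta3 = theta_eff[, 3L],
    attempted1 = attempted[, 1L], attempted2 = attempted[, 2L],
    attempted3 = attempted[, 3L],
    advanced1 = adv[, 1L], advanced2 = adv[, 2L], advanced3 = adv[, 3L],
    max_phase_attempted = 1L + adv[, 1L] + (adv[, 1L] & adv[, 2L]),
    approved_latent = approved_latent, approved_observed = approved_obs,
    phase2_deleted = deleted,
    stringsAsFactors = FALSE
  )

  structure(list(records = records, approvals = approvals, truth = truth,
                 config = cfg, seed = as.integer(seed)),
            class = "registry_sim")
}

#' @export
print.registry_sim <- function(x, ...) {
  cat(sprintf("Synthetic registry: %d records, %d programs, %d approvals (seed %d)\n",
              nrow(x$records), nrow(x$truth), nrow(x$approvals), x$seed))
  invisible(x)
}

#' Exact latent transition counts and POS from generator ground truth
#'
#' Summarises the latent Bernoulli outcomes before any censoring or record
#' deletion: how many programs attempted each phase, how many advanced, and
#' the exact latent per-phase and overall success proportions. On
#' missingness-free, censoring-free data the pipeline's
#' [tabulate_transitions()] must reproduce these counts exactly.
#'
#' @param x a `registry_sim` (or its `truth` data.frame).
#' @return A list with `counts` (a `transition_counts`), `pos_phase`
#'   (latent per-phase advancement proportions), and `pos_overall`.
#' @export
truth_summary <- function(x) {
  truth <- if (inherits(x, "registry_sim")) x$truth else x
  att <- cbind(truth$attempted1, truth$attempted2, truth$attempted3)
  adv <- cbind(truth$advanced1, truth$advanced2, truth$advanced3)
  n <- colSums(att)
  n_t <- colSums(att & !adv)
  n_app <- sum(truth$approved_latent)
  counts <- transition_counts(n = n, n_t = n_t, n_approval = n_app)
  list(counts = counts,
       pos_phase = colSums(att & adv) / n,
       pos_overall = n_app / n[1])
}

#' Write a simulated registry bundle to disk
#'
#' @param sim a `registry_sim`.
#' @param dir output directory (created if needed); writes `registry.csv`,
#'   `approvals.csv` and `truth.json`.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "registry_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_registry(sim$records, file.path(dir, "registry.csv"))
  write_approvals(sim$approvals, file.path(dir, "approvals.csv"))
  cfg <- sim$config
  cfg$snapshot_date <- format(cfg$snapshot_date)
  cfg$program_start_window <- format(cfg$program_start_window)
  ts <- truth_summary(sim)
  jsonlite::write_json(list(
    seed = sim$seed, config = unclass(cfg),
    latent = list(n = ts$counts$n, n_t = ts$counts$n_t,
                  n_approval = ts$counts$n_approval,
                  pos_phase = ts$pos_phase, pos_overall = ts$pos_overall),
    programs = sim$truth
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
  invisible(dir)
}
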