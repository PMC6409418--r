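test_that("completion rates count positive early stops as completions", {
  recs <- do.call(rbind, lapply(1:10, function(i) {
    make_record(trial_id = sprintf("T%02d", i), drug_id = sprintf("D%02d", i),
                phase_label = "P2",
                status = if (i <= 8) "completed" else "failed")
  }))
  cr <- completion_rates(recs)
  expect_equal(cr$rate[cr$phase == 2], 0.8)
  expect_equal(cr$n_concluded[cr$phase == 2], 10L)
  expect_true(is.na(cr$rate[cr$phase == 1]))  # no Phase 1 trials at all

  recs$status[1] <- "terminated_positive"
  cr2 <- completion_rates(recs)
  expect_equal(cr2$rate[cr2$phase == 2], 0.8)  # still a completion

  ongoing <- recs
  ongoing$status <- "ongoing"
  ongoing$end_date <- as.Date(NA)
  cr3 <- completion_rates(ongoing)
  expect_true(is.na(cr3$rate[cr3$phase == 2]))
})

test_that("trials per path average over paths observed in the phase", {
  recs <- do.call(rbind, lapply(1:3, function(i) {
    do.call(rbind, lapply(seq_len(i), function(k) {
      make_record(trial_id = sprintf("T%d%d", i, k),
                  drug_id = sprintf("D%02d", i), phase_label = "P1")
    }))
  }))
  tp <- trials_per_path(build_programs(recs))
  expect_equal(tp$mean_trials[tp$phase == 1], 2)  # counts 1, 2, 3
  expect_equal(tp$n_paths[tp$phase == 1], 3L)

  single <- trials_per_path(build_programs(make_record()))
  expect_equal(single$mean_trials, 1)

  # an imputed (zero-trial) Phase 2 contributes nothing to the Phase 2 mean
  r13 <- rbind(program_records("D01", "I01", 1, last_end = "2006-01-01"),
               program_records("D01", "I01", 3, last_end = "2010-01-01"))
  tp13 <- trials_per_path(build_programs(r13))
  expect_false(2L %in% tp13$phase)
})

test_that("duration medians use observed concluded trials, in years", {
  recs <- rbind(
    make_record(trial_id = "T01", start_date = "2010-01-01",
                end_date = "2011-07-02"),                      # 547 d
    make_record(trial_id = "T02", drug_id = "D02",
                start_date = "2010-01-01", end_date = "2011-01-01"), # 1 y
    make_record(trial_id = "T03", drug_id = "D03",
                start_date = "2010-01-01", end_date = "2012-01-01"), # 2 y
    make_record(trial_id = "T04", drug_id = "D04", phase_label = "P2",
                start_date = "2010-01-01", end_date = "2012-01-01",
                end_date_imputed = TRUE),                      # excluded
    make_record(trial_id = "T05", drug_id = "D05", phase_label = "P2",
                status = "ongoing", end_date = NULL)           # excluded
  )
  ds <- duration_stats(recs)
  p1 <- ds$summary[ds$summary$phase == 1, ]
  expect_equal(p1$n, 3L)
  expect_equal(p1$median_years, 547 / 365.25, tolerance = 1e-6)
  expect_false(2 %in% ds$summary$phase)  # only excluded trials there

  # even-count median and clinic time as the sum of phase medians
  recs2 <- rbind(
    make_record(trial_id = "A1", start_date = "2010-01-01",
                end_date = format(as.Date("2010-01-01") + 365)),
    make_record(trial_id = "A2", drug_id = "D02", start_date = "2010-01-01",
                end_date = format(as.Date("2010-01-01") + 731)),
    make_record(trial_id = "B1", drug_id = "D03", phase_label = "P2",
                start_date = "2010-01-01",
                end_date = format(as.Date("2010-01-01") + 731)),
    make_record(trial_id = "C1", drug_id = "D04", phase_label = "P3",
                start_date = "2010-01-01",
                end_date = format(as.Date("2010-01-01") + 1096))
  )
  ds2 <- duration_stats(recs2)
  expect_equal(ds2$summary$median_years[ds2$summary$phase == 1],
               548 / 365.25, tolerance = 1e-6)   # mean of 365 and 731
  expect_equal(ds2$clinic_time$clinic_time_years,
               sum(ds2$summary$median_years[ds2$summary$phase <= 3]))
})

test_that("terminated trials' duration gap is recovered from states", {
  # advanced program: Phase 2 trials of ~24 months; terminated: ~16 months
  mk <- function(drug, months, more_phases) {
    end2 <- as.Date("2010-01-01") + round(months * 30.4375)
    rows <- make_record(trial_id = paste0("T2-", drug), drug_id = drug,
                        phase_label = "P2", start_date = "2010-01-01",
                        end_date = format(end2))
    if (more_phases) {
      rows <- rbind(rows, make_record(
        trial_id = paste0("T3-", drug), drug_id = drug, phase_label = "P3",
        start_date = format(end2 + 100),
        end_date = format(end2 + 1000)))
    }
    rows
  }
  recs <- rbind(mk("D01", 24, TRUE), mk("D02", 23, TRUE),
                mk("D03", 16, FALSE), mk("D04", 17, FALSE))
  pr <- build_programs(recs)
  st <- classify_phase_states(pr, far_thresholds())
  tv <- terminated_vs_advanced(st, pr, phase = 2)
  expect_equal(tv$n_advanced, 2L)
  expect_equal(tv$n_terminated, 2L)
  expect_equal(tv$delta_months, 23.5 - 16.5, tolerance = 0.05)

  # identical distributions: delta ~ 0
  recs0 <- rbind(mk("D01", 20, TRUE), mk("D03", 20, FALSE))
  pr0 <- build_programs(recs0)
  tv0 <- terminated_vs_advanced(classify_phase_states(pr0, far_thresholds()),
                                pr0, phase = 2)
  expect_equal(tv0$delta_months, 0, tolerance = 0.05)

  # an empty group yields NA with counts
  recs1 <- mk("D01", 20, TRUE)
  pr1 <- build_programs(recs1)
  tv1 <- terminated_vs_advanced(classify_phase_states(pr1, far_thresholds()),
                                pr1, phase = 2)
  expect_true(is.na(tv1$delta_months))
  expect_equal(tv1$n_terminated, 0L)
})

test_that("the generator's terminated-duration gap is recovered", {
  cfg <- plain_config(n_drugs = 1200,
                      duration_gap_terminated_months = c(0, 8.1, -3.2))
  sim <- simulate_registry(cfg, seed = 55)
  pr <- build_programs(sim$records, sim$approvals)
  st <- classify_phase_states(pr, far_thresholds())
  tv2 <- terminated_vs_advanced(st, pr, phase = 2)
  expect_equal(tv2$delta_months, 8.1, tolerance = 2.5)
  tv3 <- terminated_vs_advanced(st, pr, phase = 3)
  expect_equal(tv3$delta_months, -3.2, tolerance = 2.5)
})

test_that("biomarker strata partition the phase-wise counts", {
  cfg <- registry_config(n_drugs = 250, biomarker_fraction = 0.3,
                         snapshot_date = "2049-12-31",
                         duplicate_fraction = 0)
  sim <- simulate_registry(cfg, seed = 77)
  th <- far_thresholds()
  bm <- biomarker_counts(sim$records, sim$approvals, th,
                         mode = "selection_only", date_floor = NULL)
  # per-phase partition against the unstratified tabulation
  full <- tabulate_transitions(
    classify_phase_states(build_programs(sim$records, sim$approvals), th))
  expect_equal(bm$with_biomarker$n + bm$without_biomarker$n, full$n)
  expect_equal(bm$with_biomarker$n_approval + bm$without_biomarker$n_approval,
               full$n_approval)

  # expanded definition can only grow the biomarker stratum
  ex <- biomarker_counts(sim$records, sim$approvals, th, mode = "expanded",
                         date_floor = NULL)
  expect_true(all(ex$with_biomarker$n >= bm$with_biomarker$n))

  # no flags, no biomarker stratum
  none <- sim$records
  none$biomarker_selection <- FALSE
  bm0 <- biomarker_counts(none, sim$approvals, th, mode = "selection_only",
                          date_floor = NULL)
  expect_equal(bm0$with_biomarker$n, c(0L, 0L, 0L))

  # the biomarker uplift in theta shows up in phase-by-phase estimates
  est_bio <- pos_phase(bm$with_biomarker, 1)
  est_non <- pos_phase(bm$without_biomarker, 1)
  expect_gt(est_bio$value, est_non$value - 2 * (est_bio$se + est_non$se))
})

test_that("exactly one lead indication per drug, order-invariant", {
  recs <- rbind(
    program_records("D01", "IA", c(1, 2), last_end = "2006-03-01"),
    program_records("D01", "IB", 1, last_end = "2008-01-01"),
    program_records("D02", "IA", 1, last_end = "2007-01-01")
  )
  pr <- lead_indications(build_programs(recs))
  lead <- pr$programs[pr$programs$is_lead_indication == TRUE, ]
  expect_equal(nrow(lead), 2L)
  expect_equal(lead$indication_id[lead$drug_id == "D01"], "IA")

  # single indication is trivially lead
  expect_equal(sum(lead$drug_id == "D02"), 1L)

  # exact date ties break to the lexicographically smaller indication
  tie <- rbind(program_records("D03", "IZ", 1, last_end = "2006-01-01"),
               program_records("D03", "IA", 1, last_end = "2006-01-01"))
  prt <- lead_indications(build_programs(tie))
  leadt <- prt$programs[prt$programs$is_lead_indication == TRUE, ]
  expect_equal(leadt$indication_id, "IA")

  # permutation invariance
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  pr2 <- lead_indications(build_programs(shuffled))
  expect_equal(
    sort(paste(lead$drug_id, lead$indication_id)),
    sort(paste(pr2$programs$drug_id[pr2$programs$is_lead_indication == TRUE],
               pr2$programs$indication_id[pr2$programs$is_lead_indication == TRUE])))
})

test_that("rolling windows tile the calendar and clip at the snapshot", {
  recs <- program_records("D01", "I01", c(1, 2), last_end = "2009-06-01")
  st <- classify_phase_states(build_programs(recs),
                              pos_thresholds("2015-10-31"))
  ser <- rolling_series(st, years = 2005:2015)
  expect_equal(nrow(ser), 11L * 4L)
  w2010 <- ser[ser$year == 2010, ]
  expect_equal(unique(w2010$window_start), as.Date("2008-01-01"))
  expect_equal(unique(w2010$window_end), as.Date("2010-12-31"))
  w2015 <- ser[ser$year == 2015, ]
  expect_equal(unique(w2015$window_end), as.Date("2015-10-31"))
  expect_true(all(w2015$boundary_biased))
  expect_false(any(ser$boundary_biased[ser$year < 2015]))

  # the Phase 2 observation (decisive 2009-06-01) appears in exactly the
  # windows ending 2009, 2010, 2011
  p2 <- ser[ser$measure == "phase2_3", ]
  covered <- p2$year[p2$denominator > 0 & !is.na(p2$denominator)]
  expect_equal(covered, c(2009L, 2010L, 2011L))
})

test_that("partner conditioning recovers the configured POS uplift", {
  cfg <- registry_config(n_drugs = 2500, partner_fraction = 0.4,
                         partner_effect = 1.15, biomarker_effect = 1,
                         snapshot_date = "2049-12-31",
                         indication_geom_p = 1, duplicate_fraction = 0)
  sim <- simulate_registry(cfg, seed = 19)
  pr <- build_programs(sim$records, sim$approvals)
  st <- classify_phase_states(pr, far_thresholds())
  pc <- partner_conditioning(st, pr)
  base <- 0.65 * 0.55 * 0.60
  uplift <- base * (1.15^3 - 1) * 100  # ~11 percentage points
  se_pp <- 100 * sqrt(pc$with_partner$overall$se^2 +
                        pc$without_partner$overall$se^2)
  expect_lt(abs(pc$difference_pp - uplift), 3 * se_pp)

  # degenerate stratification: everything on one side
  solo <- registry_config(n_drugs = 60, partner_fraction = 0,
                          snapshot_date = "2049-12-31")
  sims <- simulate_registry(solo, seed = 3)
  prs <- build_programs(sims$records, sims$approvals)
  pcs <- partner_conditioning(classify_phase_states(prs, far_thresholds()), prs)
  expect_null(pcs$with_partner)
  expect_true(is.na(pcs$difference_pp))
})
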