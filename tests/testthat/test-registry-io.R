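test_that("a well-formed CSV round-trips with a clean report", {
  path <- write_registry_text(c(
    registry_csv_row(trial_id = "T001"),
    registry_csv_row(trial_id = "T002", phase_label = "P2",
                     end_date = "2007-06-30"),
    registry_csv_row(trial_id = "T003", drug_id = "D02", status = "ongoing",
                     end_date = "")
  ))
  out <- read_registry(path)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$report$n_input, 3L)
  expect_equal(out$report$n_output, 3L)
  expect_s3_class(out$records$start_date, "Date")
  expect_true(is.na(out$records$end_date[3]))

  # round trip through the writer
  path2 <- tempfile(fileext = ".csv")
  write_registry(out$records, path2)
  again <- read_registry(path2)
  expect_equal(again$records, out$records)
})

test_that("impossible calendar dates are rejected with row diagnostics", {
  path <- write_registry_text(c(
    registry_csv_row(trial_id = "T001"),
    registry_csv_row(trial_id = "T002", start_date = "2001-02-30")
  ))
  out <- read_registry(path)
  expect_equal(nrow(out$records), 1L)
  expect_match(paste(out$report$diagnostics, collapse = "; "), "row 2")
  expect_match(paste(out$report$diagnostics, collapse = "; "), "2001-02-30")
})

test_that("the drop rule removes rows with unidentified sponsors", {
  rows <- c(
    registry_csv_row(trial_id = "T001"),
    registry_csv_row(trial_id = "T002", sponsor_id = ""),
    registry_csv_row(trial_id = "T003", drug_id = "D02"),
    registry_csv_row(trial_id = "T004", sponsor_id = ""),
    registry_csv_row(trial_id = "T005", drug_id = "D03")
  )
  out <- read_registry(write_registry_text(rows), drop_incomplete = TRUE)
  expect_equal(out$report$n_output, 3L)
  expect_equal(out$report$n_dropped_missing_dates_or_sponsor, 2L)
})

test_that("schema violations are hard errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("trial_id,drug_id", "T001,D01"), path)
  expect_error(read_registry(path), "missing mandatory column",
               class = "pathpos_schema_error")
  dup <- write_registry_text(c(registry_csv_row(), registry_csv_row()))
  expect_error(read_registry(dup), "duplicate",
               class = "pathpos_duplicate_key_error")
})

test_that("filtering drops pre-window records and keeps the report additive", {
  recs <- make_records(
    make_record(trial_id = "T001", start_date = "1998-01-01",
                end_date = "1999-12-31"),
    make_record(trial_id = "T002"),
    make_record(trial_id = "T003", sponsor_id = "", drug_id = "D02"),
    make_record(trial_id = "T004", drug_id = "D03")
  )
  out <- filter_records(recs, window_start = "2000-01-01")
  expect_equal(out$report$n_dropped_pre_window, 1L)
  expect_equal(out$report$n_dropped_missing_dates_or_sponsor, 1L)
  expect_equal(out$report$n_output, 2L)
  expect_false("T001" %in% out$records$trial_id)

  empty <- filter_records(recs[0, ], window_start = "2000-01-01")
  expect_equal(empty$report$n_input, 0L)
  expect_equal(empty$report$n_output, 0L)

  expect_error(filter_records(recs, window_start = "not-a-date"),
               class = "pathpos_config_error")
})

test_that("end-date imputation uses the median duration of similar trials", {
  donors <- make_records(
    make_record(trial_id = "T001", phase_label = "P2",
                start_date = "2005-01-01", end_date = "2005-04-11"),  # 100 d
    make_record(trial_id = "T002", phase_label = "P2", drug_id = "D02",
                start_date = "2005-01-01", end_date = "2005-07-20"),  # 200 d
    make_record(trial_id = "T003", phase_label = "P2", drug_id = "D03",
                start_date = "2005-01-01", end_date = "2006-02-05")   # 400 d
  )
  target <- make_record(trial_id = "T100", phase_label = "P2",
                        drug_id = "D04", start_date = "2010-01-01",
                        end_date = NULL, status = "completed")
  out <- impute_end_dates(rbind(donors, target))
  got <- out$records[out$records$trial_id == "T100", ]
  expect_equal(got$end_date, as.Date("2010-01-01") + 200L)
  expect_true(got$end_date_imputed)
  expect_equal(out$report$n_end_dates_imputed, 1L)

  # even donor count: median is the mean of the middle pair
  out2 <- impute_end_dates(rbind(donors[c(1, 3), ], target))
  got2 <- out2$records[out2$records$trial_id == "T100", ]
  expect_equal(got2$end_date, as.Date("2010-01-01") + 250L)
})

test_that("imputation falls back through coarser feature groups", {
  donors <- make_records(
    make_record(trial_id = "T001", phase_label = "P2",
                therapeutic_group = "cns", start_date = "2005-01-01",
                end_date = "2005-05-01"),   # 120 d, different group
    make_record(trial_id = "T002", phase_label = "P3", drug_id = "D02",
                start_date = "2005-01-01", end_date = "2007-01-01")
  )
  target <- make_record(trial_id = "T100", phase_label = "P2",
                        drug_id = "D04", therapeutic_group = "oncology",
                        start_date = "2010-01-01", end_date = NULL)
  out <- impute_end_dates(rbind(donors, target))
  got <- out$records[out$records$trial_id == "T100", ]
  # no oncology Phase 2 donor; falls back to the phase-level median (120 d)
  expect_equal(got$end_date, as.Date("2010-01-01") + 120L)
})

test_that("imputation leaves observed end dates alone and is idempotent", {
  recs <- make_records(
    make_record(trial_id = "T001"),
    make_record(trial_id = "T002", drug_id = "D02", end_date = NULL,
                status = "completed"),
    make_record(trial_id = "T003", drug_id = "D03", end_date = NULL,
                status = "ongoing")
  )
  once <- impute_end_dates(recs)
  expect_equal(once$report$n_end_dates_imputed, 1L)
  expect_equal(once$records$end_date[1], as.Date("2006-01-01"))
  expect_true(is.na(once$records$end_date[3]))  # censored, not repaired
  twice <- impute_end_dates(once$records)
  expect_equal(twice$report$n_end_dates_imputed, 0L)
  expect_equal(twice$records, once$records)

  single <- impute_end_dates(make_record())
  expect_equal(single$report$n_end_dates_imputed, 0L)

  hopeless <- make_record(end_date = NULL, status = "completed")
  expect_error(impute_end_dates(hopeless), class = "pathpos_imputation_error")
})

test_that("report arithmetic holds on randomised inputs", {
  set.seed(401)
  for (rep in 1:15) {
    n <- sample(3:25, 1)
    rows <- lapply(seq_len(n), function(i) {
      start <- as.Date("1998-06-01")
      make_record(
        trial_id = sprintf("T%03d", i), drug_id = sprintf("D%02d", i %% 7),
        sponsor_id = if (runif(1) < 0.2) "" else "S01",
        start_date = if (runif(1) < 0.1) NULL else format(start),
        end_date = if (runif(1) < 0.3) NULL else
          format(start + sample.int(4000, 1)),  # some end pre-2000
        status = sample(c("completed", "failed", "ongoing"), 1)
      )
    })
    recs <- do.call(rbind, rows)
    out <- filter_records(recs, window_start = "2000-01-01")
    r <- out$report
    expect_equal(r$n_output,
                 r$n_input - r$n_dropped_missing_dates_or_sponsor -
                   r$n_dropped_pre_window)
    expect_equal(nrow(out$records), r$n_output)
    # filtering is idempotent
    again <- filter_records(out$records, window_start = "2000-01-01")
    expect_equal(again$records, out$records)
  }
})

test_that("the report constructor rejects inconsistent tallies", {
  expect_error(filter_report(n_input = 3, n_output = 1),
               class = "pathpos_report_error")
  expect_error(filter_report(n_input = -1, n_output = -1),
               class = "pathpos_report_error")
})
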