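# Fixture builders: records are constructed in code, never stored on disk.

make_record <- function(trial_id = "T001", drug_id = "D01",
                        indication_id = "I01", sponsor_id = "S01",
                        sponsor_class = "industry", phase_label = "P1",
                        start_date = "2005-01-01", end_date = "2006-01-01",
                        end_date_imputed = FALSE, status = "completed",
                        therapeutic_group = "oncology",
                        biomarker_selection = FALSE,
                        biomarker_evaluation = FALSE, orphan = FALSE,
                        source_tag = "ctgov", n_nonindustry_partners = 0L) {
  data.frame(
    trial_id = trial_id, drug_id = drug_id, indication_id = indication_id,
    sponsor_id = sponsor_id, sponsor_class = sponsor_class,
    phase_label = phase_label,
    start_date = if (is.null(start_date)) as.Date(NA) else as.Date(start_date),
    end_date = if (is.null(end_date)) as.Date(NA) else as.Date(end_date),
    end_date_imputed = end_date_imputed, status = status,
    therapeutic_group = therapeutic_group,
    biomarker_selection = biomarker_selection,
    biomarker_evaluation = biomarker_evaluation, orphan = orphan,
    source_tag = source_tag,
    n_nonindustry_partners = as.integer(n_nonindustry_partners),
    stringsAsFactors = FALSE
  )
}

make_records <- function(...) do.call(rbind, list(...))

# write raw CSV text (possibly malformed) for reader tests
registry_csv_header <- paste(
  "trial_id,drug_id,indication_id,sponsor_id,sponsor_class,phase_label,",
  "start_date,end_date,end_date_imputed,status,therapeutic_group,",
  "biomarker_selection,biomarker_evaluation,orphan,source_tag,",
  "n_nonindustry_partners", sep = "")

registry_csv_row <- function(trial_id = "T001", drug_id = "D01",
                             indication_id = "I01", sponsor_id = "S01",
                             sponsor_class = "industry", phase_label = "P1",
                             start_date = "2005-01-01",
                             end_date = "2006-01-01",
                             end_date_imputed = "false",
                             status = "completed",
                             therapeutic_group = "oncology",
                             biomarker_selection = "false",
                             biomarker_evaluation = "false",
                             orphan = "false", source_tag = "ctgov",
                             n_nonindustry_partners = "0") {
  paste(trial_id, drug_id, indication_id, sponsor_id, sponsor_class,
        phase_label, start_date, end_date, end_date_imputed, status,
        therapeutic_group, biomarker_selection, biomarker_evaluation,
        orphan, source_tag, n_nonindustry_partners, sep = ",")
}

write_registry_text <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(registry_csv_header, rows), path)
  path
}

# a program's records at the given phases, one completed trial per phase,
# ends one year apart so phase order is well defined
program_records <- function(drug, ind, phases,
                            last_end = "2010-01-01",
                            last_status = "completed",
                            sponsor = "S01", group = "oncology") {
  phases <- sort(phases)
  ends <- as.Date(last_end) - rev(seq_along(phases) - 1L) * 400L
  rows <- lapply(seq_along(phases), function(i) {
    make_record(
      trial_id = sprintf("T-%s-%s-%d", drug, ind, phases[i]),
      drug_id = drug, indication_id = ind, sponsor_id = sponsor,
      phase_label = paste0("P", phases[i]),
      start_date = ends[i] - 365L, end_date = ends[i],
      status = if (i == length(phases)) last_status else "completed",
      therapeutic_group = group
    )
  })
  do.call(rbind, rows)
}

approval_row <- function(drug, ind, date = "2012-01-01") {
  data.frame(drug_id = drug, indication_id = ind,
             approval_date = as.Date(date), stringsAsFactors = FALSE)
}

far_thresholds <- function() pos_thresholds("2049-12-31")

# a config with subgroup effects switched off, so the latent advancement
# probabilities are exactly theta
plain_config <- function(theta = c(0.65, 0.55, 0.60), n_drugs = 200L,
                         snapshot_date = "2049-12-31", ...) {
  registry_config(n_drugs = n_drugs, theta = theta,
                  snapshot_date = snapshot_date,
                  indication_geom_p = 1, biomarker_effect = 1,
                  partner_effect = 1, duplicate_fraction = 0, ...)
}

fit_sim <- function(sim) {
  pos_fit(sim$records, sim$approvals,
          snapshot_date = sim$config$snapshot_date)
}
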