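# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".I", ".GRP", ".SD", "cphase", "pid", "trial_id", "sponsor_id",
  "start_date", "end_date", "drug_id", "indication_id", "therapeutic_group",
  "orphan", "sponsor_class", "n_nonindustry_partners", "phase", "state",
  "decisive_date", "approval_date", "first_start", "first_end", "status",
  "approved", "max_obs", "all_failed", "any_open", "i.approval_date",
  "i.p4_start", "n_trials", "lo", "hi", "hi_obs", "first", "years", "months",
  "max_partners", "is_lead_indication", "ongoing", "end", "start", "bio",
  "biomarker_selection", "biomarker_evaluation", "k", "phase_label",
  "p4_start", "n_concluded"
))
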