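# pathpos

Estimation of clinical trial success rates by reconstructing drug
development paths from flat trial-registry records.

## The problem

The probability of success (POS) of drug development — the chance that a
drug-indication program advances from one clinical phase to the next, or
from Phase 1 all the way to regulatory approval (the likelihood of
approval, LOA) — drives scientific and investment decisions across
biopharma. Estimating it from registry data is harder than it looks:
registry rows are flat (trial, drug, indication, sponsor) quartets, phases
of a program can be missing from the record, programs are right-censored
at the data snapshot, and whether a program quietly died or is still
running must be inferred from elapsed time.

`pathpos` implements the **path-by-path** approach: group records into
drug-indication development programs, infer each program's per-phase state,
impute interior phases that the idealized Phase 1 → 2 → 3 process implies
must have happened, and count reconstructed paths. For phase `j` with
`n^j` observed paths, `n_m^j` imputed paths, `n_ip^j` paths entirely in
progress and `n_t^j` terminated paths, the conservation law for
development paths is

    n^{j+1} = n^j + n_m^j − n_ip^j − n_t^j ,   j = 1, 2, 3

(the left side read as the reconstructed Phase j+1 total, approvals for
j = 3), and the estimators are

    POS_{j,j+1}  = n^{j+1} / (n^j + n_m^j − n_ip^j)                 path-by-path
    POS_{1,APP}  = n^APP / (n^1 + n_m^1 − n_ip^1 − n_ip^2 − n_ip^3)
    POS^p_{j,j+1} = (n^{j+1} − n_m^j) / (n^j − n_ip^j)              phase-by-phase
    POS^p_{1,APP} = Π_j POS^p_{j,j+1}

The classical phase-by-phase product is biased downward when interior
phase records are missing; the path-by-path overall estimate is not. A
program's latest observed phase is declared terminated when more than
360/540/900 days (Phases 1/2/3) have elapsed between its most recent trial
end and the snapshot; otherwise it is in progress.

Because the commercial registries this methodology targets are
proprietary, the package ships a synthetic registry generator with known
ground truth (per-phase advancement probabilities, censoring, interior
missingness, subgroup effects), so every pipeline stage is testable end to
end.

## A worked example

```r
library(pathpos)

sim <- simulate_registry(registry_config(n_drugs = 500), seed = 7)
fit <- pos_fit(sim$records, sim$approvals, snapshot_date = "2015-10-31")
summary(fit)
#> Probability of success by clinical phase (snapshot 2015-10-31 )
#>
#>                paths path-by-path % (SE %) phase-by-phase % (SE %)
#> Phase 1 to 2     694           65.7    1.8             65.7    1.8
#> Phase 2 to 3     284           56.0    2.9             56.0    2.9
#> Phase 3 to APP    29           75.9    7.9             75.9    7.9
#> Phase 1 to APP   392            5.6    1.2             27.9    3.4
#>
#> Transition counts:
#>                       Phase 1 Phase 2 Phase 3
#> paths (obs + imputed)     722     456     159
#> observed                  722     456     159
#> imputed                     0       0       0
#> in_progress                28     172     130
#> terminated                238     125       7
#> approvals: 22
```

The 722 programs visible at the snapshot yield per-phase POS estimates of
65.7%, 56.0% and 75.9% — each the ratio of reconstructed paths reaching
the next phase to paths eligible to leave the current one (programs still
entirely in progress are excluded from denominators, hence 694 rather than
722 Phase 1 paths). The overall path-by-path POS of 5.6% is the fraction
of eligible Phase 1 paths with an observed approval; it sits far below the
phase-by-phase product (27.9%) because most of these programs started too
recently to have finished all three phases — the per-phase factors
condition on completed transitions, while the path-by-path overall divides
by everything that had time to fail.

Downstream analyses take the fitted object or its pieces: rolling-window
time series (`rolling_series`), biomarker / orphan / lead-indication /
partner subgroups (`biomarker_counts`, `lead_indications`,
`partner_conditioning`), completion rates and duration summaries
(`completion_rates`, `duration_stats`, `terminated_vs_advanced`). The
file-based pipeline (`run_estimate`, `run_timeseries`) reads registry and
approval CSVs, repairs missing end dates by the median duration of similar
trials, and writes a report bundle; `inst/cli/pathpos.R` is a thin shell
wrapper over those functions.

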