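---
title: "Reconstructing drug development paths and estimating success rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing drug development paths and estimating success rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpos)
```

## The model

A *development program* is the investigation of one drug for one
indication; its registry footprint is a set of trial rows. We assume an
idealized process in which every program traverses Phases 1, 2 and 3 in
order before approval. Combined-phase trials are assigned to the later
phase (Phase 1/2 counts as Phase 2, Phase 2/3 as Phase 3). A trial that
concludes with its objectives met is *completed*; one stopped prematurely
is *failed*, except that early stops for positive results count as
completions.

Under the idealized process, observing Phases 1 and 3 of a program without
any Phase 2 record implies a Phase 2 passage that is missing from the
data, and we impute it as a success. This is the crux of the method:
estimators that use only directly observed transitions are biased downward
exactly when interior records are missing for programs that advanced.

Each program's phases are classified into states:

* **advanced** — a higher phase (or an approval) is observed;
* **terminated** — the latest observed phase, when more than
  $t_j$ days have elapsed between its most recent trial end and the data
  snapshot ($t_{1,2,3}$ = 360, 540, 900 days by default), or when every
  trial in the phase failed;
* **in progress** — the latest observed phase otherwise, including
  whenever any trial still lacks an end date;
* **missing (imputed)** — an interior phase with no records between
  observed evidence.

The Phase 3 threshold of 900 days deliberately absorbs regulatory
submission and review time, so approval is modelled as following Phase 3
directly rather than as a separate event.

### Counts and conservation

Writing $n^j$ for the number of paths with observed Phase $j$ trials,
$n^j_m$ for imputed passages, $n^j_{ip}$ for paths entirely in progress
and $n^j_t$ for terminated paths, every path present in a phase either
advances, is in flight, or terminated:

$$ n^{j+1} \;=\; n^j + n^j_m - n^j_{ip} - n^j_t, \qquad j = 1,2,3, $$

where the left-hand side is the *reconstructed total* (observed plus
imputed) in Phase $j+1$, and the right-hand side builds the Phase $j$
total from its observed and imputed parts; for $j=3$ the left side is the
approval count. The package stores both tallies (`n_obs` and `n_m`,
with `n = n_obs + n_m`) so the law is checked on independently counted
quantities, not by algebraic cancellation. Paths first observed at Phase 2
or 3 (possible in principle, though not produced by the bundled generator)
enter the bookkeeping at their first observed phase; a separate `n_entry`
tally keeps the identity exact in their presence. The tabulator asserts
the law on every run.

### Estimators

Path-by-path, both numerator and denominator count reconstructed paths,
with all-in-progress paths removed from the denominator:

$$ \mathrm{POS}_{j,j+1} = \frac{n^{j+1}+n^{j+1}_m}{n^j + n^j_m - n^j_{ip}},
\qquad
\mathrm{POS}_{1,\mathrm{APP}} =
\frac{n^{\mathrm{APP}}}{n^1 + n^1_m - n^1_{ip} - n^2_{ip} - n^3_{ip}}. $$

Phase-by-phase (the classical approach) uses directly observed programs
and transitions and multiplies across phases:

$$ \mathrm{POS}^p_{j,j+1} =
\frac{(n^{j+1}+n^{j+1}_m) - n^j_m}{n^j - n^j_{ip}}, \qquad
\mathrm{POS}^p_{1,\mathrm{APP}} = \prod_j \mathrm{POS}^p_{j,j+1}. $$

With nothing imputed and nothing censored the two coincide exactly
(telescoping), which the test suite asserts to $10^{-12}$. When advancing
programs lose their Phase 2 records with probability $m$, the path-by-path
overall estimator is unaffected (its numerator and denominator do not
involve Phase 2 observation), while the phase-by-phase product is pulled
down by roughly $(1-m)/(1-\theta_2 m)$ — at $m = 0.5$ a relative error of
about 30%. The test suite measures both over 20 generator seeds at
$m \in \{0, 0.2, 0.5\}$.

### Standard errors

Published POS tables print standard errors without stating a formula. We
use the binomial $\sqrt{p(1-p)/n}$ with $n$ the estimator's own
denominator, which reproduces the printed one-decimal SEs of large
aggregate rows (e.g. $p = 66.4\%$ on 41 040 paths gives 0.23%, printing
as 0.2). The overall phase-by-phase SE uses the first-order delta method
treating the three factors as independent; the factors share no programs
only approximately, so this SE is indicative, not exact. Each estimate
carries its numerator and denominator so any other convention can be
recomputed from the output.

## Windowed and rolling estimates

Estimating POS over short calendar windows cannot wait for whole paths, so
windowed estimates use the phase-by-phase form, restricted to phase
observations whose *decisive date* — the latest end date among the phase's
concluded trials — falls in $[t_1, t_2]$. Three conventions follow from
the data: imputed phases carry no dates and never enter a window; a
program still in progress enters the window tallies only if some trial in
the phase has concluded; approvals are dated by the program's observed
Phase 3 decisive date. Because the numerator (arrivals in Phase $j+1$) and
denominator (Phase $j$ completions) then count different program sets, a
sparse window can yield a ratio above 1; the package reports it as
computed and withholds the (meaningless) binomial SE.

`rolling_series()` computes the standard 3-year windows, January 1 of
$t-2$ through December 31 of $t$, clipping the final window at the
snapshot. Estimates in the snapshot-adjacent window are flagged
`boundary_biased`: programs that recently finished a phase and will
eventually terminate still look in-progress there, shrinking the
denominator and inflating the POS. The test suite verifies this boundary
effect appears in at least 18 of 20 seeds on stationary synthetic data.

## Registry repair choices

* **End-date imputation.** Concluded trials lacking end dates receive
  `start + median duration` of donor trials sharing the most specific
  available key, falling back through (canonical phase, therapeutic group,
  sponsor class) → (phase, group) → (phase) → all donors. Donors are
  concluded trials with non-imputed dates; even-count medians average the
  middle pair; days round half-up. Ongoing/planned trials are censored,
  never repaired. The operation is idempotent.
* **Filtering.** Records ending before the analysis window (default
  2000-01-01) and, optionally, records with missing start dates or
  unidentified sponsors are dropped, with every drop tallied in an
  additive `filter_report`.
* **Grouping.** Programs are keyed by (drug, indication) by default — POS
  is a property of a drug-indication effort; a (drug, indication, sponsor)
  key is available. The same trial listed under several sponsors enters
  its program once.
* **Approval evidence.** An approval record is authoritative; in addition,
  a Phase 4 (post-marketing) trial implies approval dated at its earliest
  start, switchable off. Approval records with no matching trials are kept
  but excluded from transition counts, as are programs with only Phase 4
  records — counting them would break the conservation law's bookkeeping.
* **Leading phases.** A program first observed at Phase 2 enters the
  analysis there; we never fabricate Phase 1 passages, since that would
  dilute the overall estimator's denominator with invented paths.
* **Tie-breaks.** Advancement evidence always wins over elapsed time or
  failed trials at a lower phase. Elapsed time uses whole days and a
  strict `>` comparison. The lead indication of a drug is its
  earliest-starting program, ties broken by earliest end date then
  lexicographic indication id.

## Subgroup analyses

Biomarker comparisons assign each program-phase to the biomarker stratum
iff at least one trial in that phase carries the flag (`selection_only`
uses patient-selection biomarkers; `expanded` adds biomarker-evaluation
trials). Because few programs use biomarkers in every phase, these
stratified counts are meaningful only phase-by-phase, and the two strata
sum to the unstratified per-phase counts. Trials observed before a
configurable floor (default 2005-01-01, when biomarker tagging became
common) are excluded so the strata cover comparable time. Orphan and
therapeutic-group labels are taken from the input columns as-is; months
and years convert at 30.4375 and 365.25 days.

## The synthetic registry generator

`simulate_registry()` draws, per drug, a truncated-geometric number of
indications; each program advances through Phases 1–3 by independent
Bernoulli draws with probabilities $\theta = (0.65, 0.55, 0.60)$ by
default, modified multiplicatively for biomarker and partnered programs.
Each attempted phase runs $1 + \mathrm{Poisson}$ trials (means 1.7, 2.0,
2.8, 3.2 across Phases 1–4) with lognormal durations (medians 1.6, 2.9,
3.8, 2.0 years); completion tags follow per-phase rates (91.4%, 81.1%,
84.9%, 87.2%), with a small share of early positive stops. Trials in a
terminated Phase 2 run 8.1 months shorter, and in a terminated Phase 3
3.2 months longer, than in advanced ones. Programs start uniformly over
2000–2012 and the registry is snapshotted on 2015-10-31: trials ending
later are emitted as ongoing without end dates, later starts are
invisible, and approvals after the snapshot are unobserved. With
probability $m$ an advancing program loses its entire Phase 2 record set —
precisely the pattern on which the two estimators disagree. A fraction of
rows is re-emitted under a co-sponsor to exercise deduplication, and some
Phase 2/3 trials carry combined labels to exercise the phase mapping.

The generator records every latent decision, and `truth_summary()` returns
the exact latent counts; on missingness-free, censoring-free data the
pipeline's tabulation must equal them exactly, which the tests assert.

What the generator does *not* emulate: calendar trends in success rates
(the latent process is stationary), disease-specific duration profiles,
sponsor-level portfolio correlation, entity-resolution noise in drug or
indication identifiers, and phase records missing other than the
whole-Phase-2 pattern. Passing tests therefore demonstrate the
*estimators' and reconstruction rules'* correctness under known
conditions, not the realism of any particular registry. Two small
systematic effects are worth knowing: the first trial of each advanced
phase is forced to complete (so a program never advances out of an
all-failed phase), which nudges realized completion rates in early phases
above their configured values; and realized duration medians sit slightly
below the configured ones because terminated-phase trials are shortened
and censoring removes the longest runs.

## Problem sizes and tolerances

The test suite checks the conservation law on 200 random registries of
20–60 drugs spanning censored and uncensored snapshots and missingness up
to 0.5; parameter recovery on 10 000 one-indication drugs (each per-phase
estimate within 3 binomial SEs of its $\theta$, the overall within 3 SEs
of 0.2145); missingness robustness and the boundary effect over 20 seeds
of 1 500 and 1 200 drugs respectively; and the worked fixtures (termination
date arithmetic, interior imputation, donor medians) exactly. Determinism
is byte-level: identical configs and seeds give identical registries, and
`run_estimate()` writes byte-identical bundles on repeated runs.

## Limitations

* The termination heuristic conflates "quietly abandoned" with "slow to
  report": a program inactive for just under the threshold counts as in
  progress, and POS estimates near the snapshot are upward-biased (hence
  the boundary flag).
* Interior imputation assumes the strict Phase 1 → 2 → 3 ladder; genuinely
  skipped phases (accelerated approvals) are counted as successes of the
  skipped phase, a documented approximation.
* The delta-method SE of the phase-by-phase product ignores dependence
  between factors.
* Lead-indication selection by earliest trial start is a convention;
  registries do not record intent.
* No entity resolution: records are grouped by exact identifier equality.
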