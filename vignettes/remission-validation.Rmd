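---
title: "Classifying remission from prescription records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying remission from prescription records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remitrx)
```

## The procedure

Prescription registries observe dispensations, not symptoms. The rule
implemented here approximates remission from major depression in three
steps, all expressed as day counts over half-open coverage intervals
`[dispense_date, dispense_date + days_supply)`:

1. **Episode onset.** The index prescription is the earliest
   antidepressant dispensation preceded by at least `washout_days` (180)
   of *observed* antidepressant-free time. "Observed" matters: the washout
   is measured from the later of the observation start and the end of any
   earlier antidepressant coverage, so a patient first seen mid-treatment
   is never assumed clean. Later antidepressant dispensations whose gap to
   the running coverage is shorter than `within_episode_gap_days` (180)
   extend the same episode; a gap at least that long ends it.

2. **Eligibility.** The episode must show strictly more than
   `min_treatment_days` (60) covered days of treatment, and the
   observation window must extend at least `followup_days` (540) past the
   episode start. Patients failing either filter — or having no episode —
   are `NOT_EVALUABLE`, with an explicit rationale
   (`NO_EPISODE`, `INSUFFICIENT_WASHOUT_OBSERVATION`,
   `MIN_TREATMENT_FAIL`, `INSUFFICIENT_FOLLOWUP`).

3. **Remission.** The anchor is the end of the *first* contiguous
   treatment course after the index. If the first antidepressant-free gap
   that follows reaches `remission_gap_days` (180) inside the observation
   window, the patient is in `REMISSION`; a new antidepressant dispensed
   sooner is a failed interruption (`NO_REMISSION`,
   `RESTART_WITHIN_GAP`); a window ending before the gap can be observed
   leaves the patient `CENSORED`.

Anchoring remission at the end of the first treatment course, rather than
at the end of the whole (possibly interrupted) episode, was a genuine
design choice. The episode definition joins courses separated by gaps
shorter than six months, so an episode can only ever end in a six-month
gap — under episode-end anchoring "restart within the remission window"
would be unsatisfiable and every evaluable patient would remit. The
first-course anchor makes the two halves of the rule symmetric: a patient
who manages six antidepressant-free months after stopping is in remission;
a patient who restarts sooner is not, even if a later interruption
succeeds. The `episode` object still records the full joined episode
(segments, interruptions, union of covered days), which is what the
minimum-treatment filter uses.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `washout_days` | 180 | days | antidepressant-free run-in defining a *new* episode |
| `min_treatment_days` | 60 | days | minimum covered treatment, strict `>` |
| `followup_days` | 540 | days | observation required after episode start, `>=` |
| `remission_gap_days` | 180 | days | antidepressant-free gap defining remission, `>=` |
| `within_episode_gap_days` | 180 | days | gaps shorter than this join courses |
| `ad_prefix` | `"N06A"` | — | ATC prefix identifying antidepressants |
| `stockpile` | `FALSE` | — | carry overlapping supply forward |

Months are fixed at 30 days (6 months = 180, 18 months = 540): calendar
months would make the classifier depend on which calendar date an episode
happens to start, for no epidemiological gain. The strictness conventions
mirror how such criteria are usually phrased: "more than 60 days" is
strict, "at least six months / 18 months" are inclusive. With stockpiling
off (the default) overlapping dispensations count each day once — the
conservative, order-invariant choice; `stockpile = TRUE` shifts unused
supply forward as some drug-era algorithms do.

The defaults of `synthetic_config()` encode the study conditions the
package validates against: true remission prevalence 0.546, classifier
sensitivity 0.925 and specificity 0.906 against the chart-review label,
three-year observation windows, 30/60/90-day supplies.

## The validity panel

`validity_report()` computes, from the 2×2 table of index rule against
reference: sensitivity, specificity, predictive values, false
positive/negative rates (the complements of sensitivity and specificity,
following the layout of the validation literature this replicates),
likelihood ratios, Cohen's kappa, the phi coefficient, Cronbach's alpha
treating the two labels as dichotomous items (population variances), the
single-threshold AUC `(S + Sp)/2`, and McNemar's chi-square.

Two Wald-interval conventions are provided. `standard` uses each
statistic's own denominator — sensitivity's interval is based on the
diseased column only — and is the defensible default. `paper_total_n`
reproduces a publication style in which the *total* sample size enters
every standard error and the interval is computed from the point estimate
already rounded to one decimal percent. The replication mode exists for
faithfulness when auditing published tables, not as a recommendation; its
intervals are generally too narrow for statistics whose true denominator
is a subset of the sample (a property-based test confirms the `standard`
intervals are never narrower).

Numerical edge cases are reported as undefined rather than coerced: a zero
denominator gives `NA`, perfect specificity gives an infinite positive
likelihood ratio, chance agreement of 1 leaves kappa undefined. Interval
bounds are clamped to `[0, 1]`; percentages are rounded half away from
zero, and only at presentation.

Published tables computed under the total-n convention can carry
last-digit inconsistencies: for the built-in reference table
(74, 5, 6, 48) the upper bounds printed for sensitivity and kappa in the
original validation exceed any normal-approximation interval consistent
with their own lower bounds by one printed unit. The package computes the
arithmetically consistent values and does not chase those digits. Two
further printed values in that panel — a McNemar entry near 58 and an AUC
of 91.2 — match no standard formula on the same counts; `remitrx` reports
the standard McNemar chi-square (0.09 on the reference table) and
`(S + Sp)/2` (91.5), and flags the difference rather than reproducing it.
The kappa interval uses the large-sample standard error
`sqrt(Po(1 - Po)/n)/(1 - Pe)`, which reproduces the published concordance
intervals; the Fleiss–Cohen–Everitt variance is available via
`se_method = "fleiss"`.

## The synthetic generator

`generate_cohort()` emulates exactly the features the validation needs:
per-patient observation windows, an index course placed after a clean
washout, and a post-treatment future controlled by the intended label —
remitting patients stay at least 30 days clear of the 180-day gap
threshold, interrupted patients restart after a gap drawn uniformly from
30–179 days and receive a second course. About 30% of patients get an
unrelated co-medication row, which the classifier must ignore. Reference
labels equal the drawn true status; discordant patients carry a
discrepancy reason drawn with the frequencies observed clinically
(dysthymia being the most common). `generate_exact_table()` fixes the
label structure cell by cell so a requested confusion table is reproduced
with equality — and the tests verify that by running the classifier on the
generated prescriptions, never by construction shortcuts.

What the generator deliberately does *not* model: drug switches and
augmentation (any antidepressant continues an episode, so agent identity
is irrelevant), dosing, refill slack and partial adherence, calendar
seasonality, age/gender structure, and ambiguous boundary gaps. Passing
tests therefore demonstrate that the classifier implements its stated
rules exactly and that the statistics are correct; they do not show that
the rule itself is valid on real dispensing data, where small refill gaps
would interact with the 180-day thresholds far more messily.

## Verification strategy and problem sizes

The suite checks the implementation against independent oracles rather
than against itself:

* a day-grid classifier that re-derives every label from a boolean
  coverage vector, compared on 300 random small timelines;
* kappa, phi and alpha recomputed from expanded 0/1 label vectors,
  compared to `1e-12` on 200 random tables of up to 500 patients;
* algebraic identities (Bayes' rule for PPV, kappa = phi under equal
  marginals, alpha = 2r/(1+r) under equal item variances);
* invariance and monotonicity properties (row order, co-medication,
  observation extension, dispensations inserted into a failed
  interruption);
* parameter recovery: over 200 replicates of 1,000 patients the mean
  recovered sensitivity and specificity sit within one percentage point of
  their targets.

These sizes were chosen to give the properties real bite while keeping the
whole suite around a quarter of a minute.

## Limitations

* The rule classifies only the first eligible episode per patient;
  relapse/recurrence analysis is out of scope.
* The washout is required to be observed, which is stricter than assuming
  patients are treatment-naive at registry entry; cohorts with short
  pre-index observation will show more `NOT_EVALUABLE` calls, not more
  remitters.
* Reference labels are consumed as given binary values; the package takes
  no position on how chart review should be conducted.
* The `paper_total_n` intervals and the rounded-estimate standard errors
  are replication devices; use `standard` for new analyses.
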