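# remitrx

Prescription-registry classification of remission from major depression,
and the statistics to validate it.

## The problem

Primary-care prescription databases record dispensations, not clinical
outcomes. Studies of major depression (MD) that rely on such databases
therefore approximate remission from dispensing patterns alone: a **new
episode** begins with an antidepressant (ATC class N06A) prescription
preceded by at least six antidepressant-free months, and a patient is in
**remission by approximation** when, after completing treatment of that
first episode, no new antidepressant is dispensed for at least six further
months. Patients who interrupt treatment for less than six months before
restarting are not in sustained remission.

`remitrx` is for pharmacoepidemiologists who use, or want to validate, this
kind of database definition. It provides:

* a deterministic episode/remission classifier over dispensing records,
  with explicit day-count criteria (180-day washout, strictly more than 60
  covered treatment days, at least 540 days of follow-up, 180-day remission
  gap — all configurable);
* the diagnostic-validity panel used to compare the database rule against
  chart-review reference labels;
* a synthetic pharmacy-claims generator with a controllable
  misclassification structure, so the entire pipeline can be exercised and
  audited without access to patient data.

## The statistics

For the 2×2 table of the database rule (index test) against chart review
(reference), with cells tp, fp, fn, tn and n = tp+fp+fn+tn:

* sensitivity S = tp/(tp+fn), specificity Sp = tn/(tn+fp), predictive
  values PPV = tp/(tp+fp), NPV = tn/(tn+fn); false-positive rate 1−S,
  false-negative rate 1−Sp; Wald 95% intervals under two conventions
  (each statistic's own denominator, or the total n as printed in some
  validation studies);
* likelihood ratios PPR = S/(1−Sp) and NPR = (1−S)/Sp;
* Cohen's kappa κ = (Po−Pe)/(1−Pe) with a large-sample interval,
  the phi coefficient (Pearson correlation of the two binary labels),
  Cronbach's alpha for two dichotomous items, McNemar's χ², and the
  single-threshold AUC (S+Sp)/2;
* the design-stage sample size n = ⌈z²p(1−p)/d²⌉ for estimating a
  prevalence p to half-width d.

## Worked example

Generate a 133-patient validation sample whose classifier-vs-chart-review
structure is the 2×2 table (74, 5, 6, 48), classify it from the raw
prescriptions, and compute the validity panel:

```r
library(remitrx)

coh   <- generate_exact_table(74, 5, 6, 48, seed = 1)
calls <- classify_cohort(coh$timelines)
calls
#> <remission_calls> 133 patient(s): 79 remission, 54 no remission, 0 not evaluable
#>   prevalence among evaluable: 59.4% (95% CI 51.1 - 67.7)

validity_report(confusion_table(calls, coh$assessments),
                ci_convention = "paper_total_n")
#> Validity report (n = 133, 11 discordant; CI convention: paper_total_n)
#>   index\reference   positive  negative
#>   positive                74         5
#>   negative                 6        48
#>
#>   Sensitivity                 92.5%  (88.0 - 97.0)
#>   Specificity                 90.6%  (85.6 - 95.6)
#>   Positive predictive value   93.7%  (89.6 - 97.8)
#>   Negative predictive value   88.9%  (83.6 - 94.2)
#>   False positives              7.5%  (3.0 - 12.0)
#>   False negatives              9.4%  (4.4 - 14.4)
#>   Cronbach's alpha            90.6%
#>   Area under the curve        91.5%
#>   Kappa (Cohen)               82.8%  (73.1 - 92.5)
#>   Pearson correlation (phi)   82.8%
#>   McNemar chi-square           0.1   (p = 0.763)
#>   Positive likelihood ratio    9.8
#>   Negative likelihood ratio    0.1
```

Reading: of 80 patients in remission by chart review, the database rule
recovered 74 (sensitivity 92.5%); of 53 not in remission it correctly kept
48 negative (specificity 90.6%). A positive database call multiplies the
pre-test odds of true remission by 9.8; chance-corrected agreement is
κ = 0.83. The 79 positive calls among 133 give the cohort prevalence shown
with its Wald interval.

Individual patients can be inspected with `classify_remission()` /
`detect_index_episode()`, files read and written with
`read_prescriptions()`, `read_assessments()`, `write_calls()`, and a thin
command-line front end (`exec/remitrx`) exposes `simulate`, `classify`,
`validate` and `replicate` subcommands over CSV/YAML/JSON files.

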