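Package: remitrx
Title: Prescription-Based Classification of Remission from Major Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies remission from a first major-depression episode using
    only longitudinal antidepressant dispensing records: an episode begins with
    an antidepressant prescription preceded by six observed antidepressant-free
    months, and a patient is in remission when treatment ends and no new
    antidepressant is dispensed for at least six further months. Includes the
    diagnostic-validity toolkit used to validate such database definitions
    against chart-review reference labels (sensitivity, specificity, predictive
    values, likelihood ratios, Cohen's kappa, phi, Cronbach's alpha for two
    dichotomous items, McNemar's test, Wald intervals, prevalence sample-size),
    and a synthetic pharmacy-claims generator so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
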