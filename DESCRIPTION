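Package: ltxcdss
Title: Rule-Based Clinical Decision Support for Lung Transplant Candidate Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale clinical decision support engine for lung transplant
    (LTx) candidate management: a declarative knowledge base of IF-THEN-ELSE
    eligibility rules with three-valued (true/false/unknown) condition logic, a
    forward-chaining inference engine with explanation traces and missing-data
    requests, a six-point candidate-management workflow over patient statuses,
    ABO/Rh donor-recipient blood-group matching, diagnostic-accuracy evaluation
    (confusion matrices with exact Clopper-Pearson confidence intervals), and
    survey psychometrics (Lawshe content-validity ratio with item retention,
    Cronbach's alpha, PSSUQ subscale scoring). Includes synthetic-data
    generators producing referral cohorts with independent gold-standard
    eligibility labels, expert-survey matrices, and Likert matrices with
    tunable reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
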