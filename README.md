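# ltxcdss

A desk-scale clinical decision support engine for lung-transplant (LTx)
candidate management, aimed at clinical-informatics researchers and
transplant teams who want referral-eligibility logic that is declarative,
inspectable, and testable rather than buried in application code.

Selecting lung-transplant candidates is a multi-stage decision: general
referral criteria (age band, end-stage lung disease with expected survival
below 50% despite optimal treatment), functional grading (NYHA class I–IV),
diagnosis confirmation, and disease-specific criteria — for COPD, a
spirometry flag (FEV1, % predicted), a history of severe dyspnea, recurrent
hospitalization, and NYHA class III/IV. `ltxcdss` encodes such criteria as
IF–THEN–ELSE production rules in YAML/JSON *knowledge packs* and evaluates
them with a forward-chaining inference engine.

The core pieces:

* **Three-valued rule logic.** Antecedents are trees of atoms
  (`fact op value`) under `all`/`any`/`not`, evaluated in Kleene strong
  logic: a missing fact is *unknown*, `unknown AND false = false`,
  `unknown AND true = unknown`, `NOT unknown = unknown`. A definite verdict
  is stable under later refinement of unknowns, so the engine can defer a
  rule and ask for data instead of guessing — absence of evidence is never
  treated as `false`.
* **Forward chaining to fixpoint** with single firing per rule (guaranteed
  termination), monotone derived facts (a conflicting assertion is a loud
  error), full fired-rule traces, and `explain()` trees from any conclusion
  down to the input facts.
* **Six-point candidate workflow** over the statuses
  `referred → preassessment → referred_to_committee → waiting_list →
  transplanted` (with a follow-up self-loop and delisting exit), with an
  audit log on every transition.
* **ABO/Rh donor matching** (`identical_only` or the standard compatibility
  matrix O→{O,A,B,AB}, A→{A,AB}, B→{B,AB}, AB→{AB}; Rh optionally strict).
* **Evaluation mathematics.** Confusion-matrix metrics
  `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)`,
  `specificity = TN/(TN+FP)` with exact Clopper–Pearson intervals
  (`qbeta(α/2, x, n−x+1)`, `qbeta(1−α/2, x+1, n−x)`).
* **Survey psychometrics.** Lawshe content-validity ratio
  `CVR = (n_e − N/2)/(N/2)` with an editable critical-value table and a
  borderline band in item retention; Cronbach's alpha; PSSUQ subscale
  scoring (system usefulness, information quality, interface quality,
  overall).
* **Synthetic-data generators** for referral cohorts with independently
  computed gold eligibility labels, expert content-validity surveys, and
  Likert matrices with a target reliability — every module is testable
  offline.

## Worked example

A COPD referral with every criterion satisfied:

```r
library(ltxcdss)
pack <- builtin_referral_pack()   # 13 rules over 4 decision levels
res <- infer(list(age = 50, ESLD = TRUE, survival_lt_50pct = TRUE,
                  advanced_despite_treatment = TRUE,
                  diagnosis_confirmed = TRUE, disease_permitted = TRUE,
                  FEV1_flag = TRUE, dyspnea_history = TRUE,
                  recurrent_hospitalization = TRUE,
                  nyha_symptoms = "daily-activity-only"), pack)
print(res)
```

```
<inference over pack 'imamltx-referral'>
  fired rules (9): age_band, esld_triplet, general_criteria, nyha_class_III,
    dx_verified, disease_permitted, diagnosis_criteria, nyha_advanced, copd_referral
  conclusions: referral-criteria-met, general-criteria-met, diagnosis-confirmed
  derived: age_criterion=TRUE, esld_criterion=TRUE, general_criteria_met=TRUE,
    nyha_class=III, dx_criterion=TRUE, disease_criterion=TRUE,
    diagnosis_criteria_met=TRUE, nyha_advanced=TRUE, referral_criteria_met=TRUE
  [recommend] the patient has the criteria of referral (copd_referral)
```

The symptom description ("symptoms during daily activity, asymptomatic at
rest") was classified NYHA class III, which satisfied the advanced-NYHA
criterion, which closed the four-way COPD conjunction. The explanation tree
makes that chain explicit:

```r
explain(res, "referral-criteria-met")
#> [rule copd_referral] => referral_criteria_met = TRUE
#>   FEV1_flag = TRUE (input)
#>   dyspnea_history = TRUE (input)
#>   recurrent_hospitalization = TRUE (input)
#>   [rule nyha_advanced] => nyha_advanced = TRUE
#>     [rule nyha_class_III] => nyha_class = III
#>       nyha_symptoms = daily-activity-only (input)
```

Evaluating a 59-patient validation table (28 TP, 9 FN, 0 FP, 22 TN):

```r
cm <- confusion_matrix(tp = 28, fn = 9, fp = 0, tn = 22)
accuracy(cm)     #> accuracy: 84.75% (73.01-92.78%; 95% CI, clopper-pearson)
sensitivity(cm)  #> sensitivity: 75.68% (58.80-88.23%; 95% CI, clopper-pearson)
specificity(cm)  #> specificity: 100.00% (84.56-100.00%; 95% CI, clopper-pearson)
```

A command-line interface wraps the same functions
(`inst/scripts/ltxcdss`): subcommands `assess`, `advance`, `match-donor`,
`evaluate`, `report`, `survey`, `simulate`, `validate-kb`.

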