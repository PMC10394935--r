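---
title: "Methods: rule-based candidate assessment and its evaluation mathematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based candidate assessment and its evaluation mathematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltxcdss)
```

`ltxcdss` models lung-transplant candidate assessment as a declarative
rule system plus the statistics needed to evaluate such a system. This
vignette explains the model and its assumptions, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices made where the design was genuinely open.

## The rule model

A *knowledge pack* is data, not code: a fact dictionary (name → kind), an
ordered list of IF–THEN–ELSE rules, and a map from conclusion tags to the
boolean facts that carry them. Rule antecedents are condition trees whose
leaves compare one fact to an operand (`eq`, `ne`, `lt`, `le`, `gt`, `ge`,
`in_set`) and whose interior nodes are `all`, `any`, `not`.

Clinical data are chronically incomplete, so conditions evaluate in Kleene
three-valued logic. A fact that is absent (or recorded `NA`) is *unknown*;
unknown propagates through connectives exactly as strong Kleene tables
dictate (`unknown AND false = false`, `unknown AND true = unknown`,
`unknown OR true = true`, `NOT unknown = unknown`). Two consequences drive
the engine's safety behaviour:

* a **definite** verdict (true or false) can never be changed by learning
  the value of a fact that was unknown — so settling a rule early is sound;
* an **unknown** verdict identifies exactly which atoms blocked it — so the
  engine can emit targeted data requests instead of a wrong default.

A type-mismatched comparison under an ordering comparator (say, a string
where a number is expected) evaluates to unknown rather than raising: at
inference time a malformed fact is equivalent to no information, and the
validation layer (`validate_record()`) is the place where it is reported as
`present-invalid`. Equality across kinds, by contrast, is definitely false.

## Forward chaining

`infer()` iterates over the not-yet-settled rules in priority order (priority
defaults to the rule's decision level, ties broken by pack order) until a
full pass settles nothing. A definitely-true antecedent fires the rule's
`then` actions; definitely false applies the `else` actions; unknown defers
the rule. Policy decisions the published description of such systems leaves
open, fixed here as engine policy:

* **Single firing.** Each rule fires at most once. With monotone facts this
  bounds passes by the rule count and guarantees termination; the system
  being modelled is a chain toward a final decision, not a
  retraction/truth-maintenance system.
* **Conflicts are errors.** A derived fact may never overwrite an input or
  derived value with a different one; the engine stops and names both
  sources. In a clinical setting a contradictory knowledge base should fail
  loudly, not tie-break silently.
* **`else` means definitely false.** Else-actions do not run on unknown —
  otherwise missing data would masquerade as a negative finding.
* **Data requests.** Facts whose unknown-ness still blocks rules at fixpoint,
  plus anything named by explicit `request_data` actions, are reported so the
  caller knows what to measure next.

The correctness of this loop is tested two independent ways: condition
evaluation against an exhaustive truth-table oracle over all
$\{t,f,u\}^k$ assignments, and whole-engine conclusions against a
brute-force closure oracle (repeated full scanning, no firing bookkeeping)
on a thousand random packs.

## The bundled referral pack

`builtin_referral_pack()` encodes the published referral-investigation rules
as 13 rules over four decision levels: the general age/ESLD criteria, the
four mutually exclusive NYHA classification rules, diagnosis confirmation,
and the COPD-specific conjunction (FEV1 flag AND dyspnea history AND
recurrent hospitalization AND NYHA III/IV) that concludes
`referral-criteria-met`.

Two printed rules needed interpretation, and both are exposed as pack
parameters rather than baked in:

* the source prints the age rule as `age >= 65 and age >= 14`, which as a
  band is unsatisfiable in one direction and clinically nonsensical; it is
  encoded as `age_min ≤ age ≤ age_max` with defaults 14 and 65;
* the FEV1 criterion is printed as `FEV1 > 35%` and is encoded exactly as
  printed, but the comparator and threshold are arguments
  (`fev1_comparator`, `fev1_threshold`) because the printed direction is at
  odds with usual COPD referral practice (severe obstruction, i.e. *low*
  FEV1, indicates referral). The engine is agnostic; the pack is data.

The centre-specific permitted-disease list behind the third-level rule is
not published; the pack models it as a boolean input fact
(`disease_permitted`) a centre can derive however it wishes.

## The six-point workflow

The candidate-management workflow is a state machine over the five statuses
with six decision points (referral, initial assessment, committee review,
waiting-list placement, follow-up, donor-day selection). Committee review
and list placement share the `referred_to_committee → waiting_list` edge —
approval and placement are one status change. Follow-up is a self-loop on
`waiting_list` whose failure exits with reason `"delisted"`; `transplanted`
is terminal. Point names are configurable defaults because the original
model's labels are not published. Only referral rules ship in the bundled
pack; the other stages are extension points whose stage facts
(`committee_approved`, `donor_match_confirmed`, ...) can equally be supplied
as recorded clinical sign-off, which is how the tests drive them.

## Evaluation mathematics

Diagnostic metrics use the standard definitions with exact Clopper–Pearson
95% intervals from beta quantiles. The interval method is a package choice:
the published evaluation reports bounds without naming a method, and the
exact method reproduces all four printed bounds to the printed precision
(verified numerically before the golden tests were frozen — e.g. 50/59
successes give 73.01–92.78%). `stats::binom.test` serves as an independent
cross-check in the tests, never as the implementation. Exact intervals are
conservative; simulated coverage at $p \in \{0.2, 0.5, 0.85\}$,
$n \in \{20, 59\}$ stays above the nominal 95%.

For the usability questionnaire, respondent subscale scores are means of the
items mapped to each subscale (the 16-item Version-3 layout is the default
map, fully overridable); pooled statistics are across-respondent mean,
median, and sample SD. The published subscale table is reproduced from
subscale-level inputs because item-level responses are not available. One
caveat is documented in the tests: the printed per-respondent scores
reproduce the printed means exactly but the printed SDs only to within one
unit in the third decimal, because the source table mixes rounded (5.33) and
unrounded (16/3) values; the golden tests therefore allow ±0.002 on the SDs.

Content-validity retention treats both thresholds as caller parameters. The
Lawshe critical-value table ships as an editable CSV rather than code, and
the mean-score rule keeps an explicit *borderline* class for means in
[3.5, 3.6): the published retention narrative states both "3.6 and above
confirmed" and "less than 3.5 discarded" on a three-point scale, which
leaves the gap (and the scale) internally inconsistent, so the package
refuses to guess.

## Synthetic data: what it emulates, and what it does not

`generate_cohort()` emulates a referral cohort with the published 59-patient
status and blood-group composition as default mixes, a configurable
eligibility prevalence (default 37/59, the published evaluation mix), and a
missing-fact rate. Eligible patients satisfy all four COPD criteria
(FEV1 drawn uniformly on (36, 80) as the pack encodes the flag, symptom
grades III/IV); ineligible patients violate a uniformly chosen non-empty
subset. Gold labels are computed by `referral_oracle()`, a straight-line
re-statement of the conjunction that deliberately shares no code with the
condition/engine machinery, *before* missingness is injected — labels stay
well-defined and the engine is graded on abstention, not forced guesses.
All randomness flows from one explicit seed through a local RNG state, so
outputs are bit-identical per seed and the caller's RNG stream is untouched.

What the generator does **not** model: realistic clinical value
distributions (lab ranges, spirometry curves, correlated comorbidities),
inter-fact correlation, or drift between centres. Passing the
engine-vs-oracle property on these cohorts shows the engine implements the
encoded criteria exactly; it says nothing about whether the criteria
themselves fit any real population.

`generate_survey()` draws expert ratings with per-item essential
probabilities (essential counts are Binomial(N, p)). The default 63-item
vector (55 items at 0.99, 8 at 0.25) was fixed once by binomial tail
arithmetic so that an 8-expert panel at the tabulated critical value
(CVR ≥ 0.75, i.e. 7 of 8) retains on average 54.9 items — near, not exactly,
55, since a 0.99-item still fails occasionally; the tests bound the count
accordingly. `generate_likert()` uses a one-factor model with the common
loading solved from the Spearman–Brown relation for the target alpha;
rounding to the discrete scale attenuates recovered alpha by roughly 0.007
at the 0.936 default target, well inside the ±0.03 recovery tolerance used
in the tests.

## Numerical and interface choices

* Percentages print to 2 decimals and cohort-report percentages to 1,
  matching the reporting style of the evaluation being reproduced; internal
  values keep full precision.
* Pack files round-trip bit-identically through YAML and JSON; whole numbers
  read back from JSON are normalised to doubles so the two formats agree.
* CSV cells: booleans `true`/`false`, unknown as the empty cell.
* The lint contradiction check enumerates candidate values per referenced
  fact (every operand, numeric neighbours of thresholds, an
  out-of-vocabulary string, unknown) rather than treating atoms as
  independent booleans; this is exact for the comparator vocabulary and
  does not false-flag the mutually exclusive NYHA rules. Pairs spanning more
  than eight facts are skipped with an explicit note.
* Problem sizes in the test suite (10⁴-patient engine-vs-oracle sweeps,
  1 000 random packs and conditions, 10⁴-replicate coverage simulations,
  100-replicate reliability recovery) were chosen as the smallest sizes at
  which the binomial/sampling bounds in the assertions are meaningful.

## Known limitations

* Only the printed referral rules ship; the production system's remaining
  rule base (~450 rules) is proprietary, and the pack format is the
  extension point.
* The engine is deliberately not a truth-maintenance system: no retraction,
  no probabilistic reasoning, no backward chaining.
* Donor matching ranks by blood-group exactness and optional waiting time
  only; HLA, size matching, and allocation scores are out of scope.
* The eight data-schema category names are placeholders; the original domain
  labels are unpublished.
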