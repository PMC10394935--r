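name: imamltx-referral
version: '1.0'
facts:
  age: number
  age_criterion: boolean
  ESLD: boolean
  survival_lt_50pct: boolean
  advanced_despite_treatment: boolean
  esld_criterion: boolean
  general_criteria_met: boolean
  nyha_symptoms: string
  nyha_class: string
  diagnosis_confirmed: boolean
  disease_permitted: boolean
  dx_criterion: boolean
  disease_criterion: boolean
  diagnosis_criteria_met: boolean
  fev1_pct: number
  FEV1_flag: boolean
  dyspnea_history: boolean
  recurrent_hospitalization: boolean
  nyha_advanced: boolean
  referral_criteria_met: boolean
conclusions:
  referral-criteria-met: referral_criteria_met
  general-criteria-met: general_criteria_met
  diagnosis-confirmed: diagnosis_criteria_met
metadata:
  disease_coverage: COPD
  parameters:
    age_min: 14.0
    age_max: 65.0
    fev1_threshold: 35.0
    fev1_comparator: gt
  notes: Referral-investigation rules across four decision levels; the FEV1 comparator/threshold
    and age band are pack parameters, not engine behaviour.
rules:
- id: age_band
  level: 1
  category: referral_criteria
  priority: 1
  if:
    all:
    - fact: age
      op: ge
      value: 14.0
    - fact: age
      op: le
      value: 65.0
  then:
  - assert: age_criterion
    value: yes
  else:
  - assert: age_criterion
    value: no
  - alert: patient is outside the age eligibility band
- id: esld_triplet
  level: 1
  category: referral_criteria
  priority: 1
  if:
    all:
    - fact: ESLD
      op: eq
      value: yes
    - fact: survival_lt_50pct
      op: eq
      value: yes
    - fact: advanced_despite_treatment
      op: eq
      value: yes
  then:
  - assert: esld_criterion
    value: yes
  else:
  - assert: esld_criterion
    value: no
- id: general_criteria
  level: 1
  category: referral_criteria
  priority: 1
  if:
    all:
    - fact: age_criterion
      op: eq
      value: yes
    - fact: esld_criterion
      op: eq
      value: yes
  then:
  - assert: general_criteria_met
    value: yes
  else:
  - assert: general_criteria_met
    value: no
  - alert: general referral criteria not met
- id: nyha_class_I
  level: 2
  category: referral_criteria
  priority: 2
  if:
    fact: nyha_symptoms
    op: eq
    value: none
  then:
  - assert: nyha_class
    value: I
- id: nyha_class_II
  level: 2
  category: referral_criteria
  priority: 2
  if:
    fact: nyha_symptoms
    op: eq
    value: normal-activity
  then:
  - assert: nyha_class
    value: II
- id: nyha_class_III
  level: 2
  category: referral_criteria
  priority: 2
  if:
    fact: nyha_symptoms
    op: eq
    value: daily-activity-only
  then:
  - assert: nyha_class
    value: III
- id: nyha_class_IV
  level: 2
  category: referral_criteria
  priority: 2
  if:
    fact: nyha_symptoms
    op: eq
    value: at-rest
  then:
  - assert: nyha_class
    value: IV
- id: dx_verified
  level: 3
  category: referral_criteria
  priority: 3
  if:
    fact: diagnosis_confirmed
    op: eq
    value: yes
  then:
  - assert: dx_criterion
    value: yes
  else:
  - assert: dx_criterion
    value: no
  - recommend: verify diagnosis with tests and disease history
- id: disease_permitted
  level: 3
  category: referral_criteria
  priority: 3
  if:
    fact: disease_permitted
    op: eq
    value: yes
  then:
  - assert: disease_criterion
    value: yes
  else:
  - assert: disease_criterion
    value: no
- id: diagnosis_criteria
  level: 3
  category: referral_criteria
  priority: 3
  if:
    all:
    - fact: dx_criterion
      op: eq
      value: yes
    - fact: disease_criterion
      op: eq
      value: yes
  then:
  - assert: diagnosis_criteria_met
    value: yes
  else:
  - assert: diagnosis_criteria_met
    value: no
- id: fev1_flag
  level: 4
  category: referral_criteria
  priority: 4
  if:
    fact: fev1_pct
    op: gt
    value: 35.0
  then:
  - assert: FEV1_flag
    value: yes
  else:
  - assert: FEV1_flag
    value: no
- id: nyha_advanced
  level: 4
  category: referral_criteria
  priority: 4
  if:
    fact: nyha_class
    op: in_set
    value:
    - III
    - IV
  then:
  - assert: nyha_advanced
    value: yes
  else:
  - assert: nyha_advanced
    value: no
- id: copd_referral
  level: 4
  category: referral_criteria
  priority: 4
  if:
    all:
    - fact: FEV1_flag
      op: eq
      value: yes
    - fact: dyspnea_history
      op: eq
      value: yes
    - fact: recurrent_hospitalization
      op: eq
      value: yes
    - fact: nyha_advanced
      op: eq
      value: yes
  then:
  - assert: referral_criteria_met
    value: yes
  - recommend: the patient has the criteria of referral
  else:
  - assert: referral_criteria_met
    value: no
  - alert: COPD referral criteria not met
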