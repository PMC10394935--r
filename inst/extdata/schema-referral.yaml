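# Default referral data schema: items, value kinds, and eight placeholder
# category names (the original eight domain labels are not published).
items:
  - {name: age, kind: number, category: demographics}
  - {name: sex, kind: string, category: demographics}
  - {name: blood_group, kind: string, category: demographics}
  - {name: diagnosis, kind: string, category: diagnosis}
  - {name: diagnosis_confirmed, kind: boolean, category: diagnosis}
  - {name: disease_permitted, kind: boolean, category: diagnosis}
  - {name: ESLD, kind: boolean, category: disease_severity}
  - {name: survival_lt_50pct, kind: boolean, category: disease_severity}
  - {name: advanced_despite_treatment, kind: boolean, category: disease_severity}
  - {name: nyha_symptoms, kind: string, category: functional_status}
  - {name: nyha_class, kind: string, category: functional_status}
  - {name: fev1_pct, kind: number, category: pulmonary_function}
  - {name: FEV1_flag, kind: boolean, category: pulmonary_function}
  - {name: dyspnea_history, kind: boolean, category: symptoms}
  - {name: recurrent_hospitalization, kind: boolean, category: clinical_history}
  - {name: status, kind: string, category: administrative}
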