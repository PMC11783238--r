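# Default variable registry for the lung-cancer detection cohort.
# Order is canonical: outcome first, demographics, then the 20-lab panel.
# Reference intervals follow clinical guideline reference ranges (95% CI);
# a missing `low` encodes a one-sided upper limit ("< high").
- name: LC
  kind: outcome
  states: [non-LC, LC]
  unit: ''
  lab: false
- name: age
  kind: continuous
  unit: years
  lab: false
- name: sex
  kind: discrete
  states: [female, male]
  unit: ''
  lab: false
- name: smoking
  kind: discrete
  states: [never, ever]
  unit: ''
  lab: false
- name: ALAT
  kind: continuous
  unit: U/L
  lab: true
  reference:
    male: [10, 70]
    female: [10, 45]
- name: Albumin
  kind: continuous
  unit: g/L
  lab: true
  reference: [34, 45]
- name: Amylase
  kind: continuous
  unit: U/L
  lab: true
  reference: [10, 65]
- name: Alkaline_phosphatase
  kind: continuous
  unit: U/L
  lab: true
  reference: [35, 105]
- name: Basophils
  kind: continuous
  unit: 10^9/L
  lab: true
  reference: [.na.real, 0.02]
- name: Bilirubin
  kind: continuous
  unit: umol/L
  lab: true
  reference: [5, 25]
- name: CRP
  kind: continuous
  unit: mg/L
  lab: true
  reference: [.na.real, 6]
- name: Calcium
  kind: continuous
  unit: mmol/L
  lab: true
  reference: [2.15, 2.51]
- name: Eosinophils
  kind: continuous
  unit: 10^9/L
  lab: true
  reference: [.na.real, 0.05]
- name: Hemoglobin
  kind: continuous
  unit: mmol/L
  lab: true
  reference:
    male: [8.3, 10.5]
    female: [7.3, 9.5]
- name: INR
  kind: continuous
  unit: ''
  lab: true
  reference: [.na.real, 1.2]
- name: Potassium
  kind: continuous
  unit: mmol/L
  lab: true
  reference: [3.5, 4.4]
- name: Creatinine
  kind: continuous
  unit: mmol/L
  lab: true
  reference:
    male: [60, 105]
    female: [45, 90]
- name: LDH
  kind: continuous
  unit: U/L
  lab: true
  reference: [115, 255]
- name: Leucocytes
  kind: continuous
  unit: 10^9/L
  lab: true
  reference: [3.5, 8.8]
- name: Lymphocytes
  kind: continuous
  unit: 10^9/L
  lab: true
  reference: [1.0, 4.0]
- name: Monocytes
  kind: continuous
  unit: 10^9/L
  lab: true
  reference: [0.2, 0.8]
- name: Sodium
  kind: continuous
  unit: mmol/L
  lab: true
  reference: [137, 145]
- name: Neutrophils
  kind: continuous
  unit: 10^9/L
  lab: true
  reference: [1.5, 7.5]
- name: Platelets
  kind: continuous
  unit: 10^9/L
  lab: true
  reference:
    male: [145, 350]
    female: [165, 390]
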