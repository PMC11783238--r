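# Data-driven (minimum description length) discretization cutpoints for the
# 20-lab panel as published for the complete (0% injected missingness)
# cohort. An empty cutpoint list is the single-bin "ALL" scheme. Age is not
# part of the published table; it is discretized from data when this scheme
# is re-learned, and is absent here.
ALAT: [15.5, 24.5]
Albumin: [41.5]
Amylase: []
Alkaline_phosphatase: [84.5]
Basophils: [0.05]
Bilirubin: [7.5]
CRP: [3.05, 13.50]
Calcium: [2.40]
Eosinophils: [0.10]
Hemoglobin: [8.05, 9.25]
INR: [0.80]
Potassium: []
Creatinine: [68.5]
LDH: [187.5, 212.5, 275.5, 417.5]
Leucocytes: [6.2, 7.9, 11.2]
Lymphocytes: []
Monocytes: [0.7]
Sodium: [135.5, 138.5]
Neutrophils: [3.5, 5.1, 7.0]
Platelets: [251.5, 342.5]
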