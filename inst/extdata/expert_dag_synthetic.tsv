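# Synthetic reconstruction of an expert-elicited DAG for lung-cancer
# detection from routine blood tests. It follows the published narrative
# pattern -- demographics feed the outcome, the outcome feeds every
# laboratory analyte, and a handful of demographic->lab links reflect known
# physiology (sex-specific reference intervals, smoking effects on
# inflammatory counts). The original expert edge set is not recoverable
# from the source text, so this file is an editable approximation, not
# ground truth.
# parent	child
age	LC
sex	LC
smoking	LC
LC	ALAT
LC	Albumin
LC	Amylase
LC	Alkaline_phosphatase
LC	Basophils
LC	Bilirubin
LC	CRP
LC	Calcium
LC	Eosinophils
LC	Hemoglobin
LC	INR
LC	Potassium
LC	Creatinine
LC	LDH
LC	Leucocytes
LC	Lymphocytes
LC	Monocytes
LC	Sodium
LC	Neutrophils
LC	Platelets
age	ALAT
age	Albumin
age	Creatinine
sex	ALAT
sex	Hemoglobin
sex	Creatinine
sex	Platelets
smoking	CRP
smoking	Leucocytes
smoking	Neutrophils
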