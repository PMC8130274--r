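group	query
CDASH vital signs	Body height
CDASH vital signs	Body Weight
CDASH vital signs	Diastolic BP
CDASH vital signs	Systolic BP
CDASH vital signs	Pulse
CDASH vital signs	Body Temperature
Most frequent LOINC codes	Creatinine
Most frequent LOINC codes	Hemoglobin
Most frequent LOINC codes	Potassium
Most frequent LOINC codes	Glucose
Most frequent LOINC codes	Sodium
Most frequent LOINC codes	Urea nitrogen
Ischaemic heart disease	Myocardial infarction
Ischaemic heart disease	Coronary Artery Bypass Surgery
Ischaemic heart disease	Angina Pectoris
Ischaemic heart disease	Myocardial Ischemia
Ischaemic heart disease	Coronary heart disease
Ischaemic heart disease	Coronary revascularization
Stroke	Cerebrovascular accident
Stroke	Hemorrhage
Stroke	Transient Ischemic Attack
Stroke	Muscle Weakness
Stroke	Grip strength test left hand
Stroke	Dysarthria
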