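id	label
therapy	therapy
medical_procedure	medical procedure
medical_test	medical test
invasive_test	invasive test
health_assessment	health assessment
medical_diagnosis	medical diagnosis
oxygen_therapy	oxygen therapy
lung_transplant	lung transplant
pulmonary_rehab	pulmonary rehabilitation
antifibrotic_therapy	antifibrotic therapy
bronchoscopy	bronchoscopy
spirometry	spirometry
lung_biopsy	lung biopsy
physical_exam	physical exam
differential_diagnosis	differential diagnosis
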