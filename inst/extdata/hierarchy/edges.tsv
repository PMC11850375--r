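child	parent
oxygen_therapy	therapy
lung_transplant	therapy
pulmonary_rehab	therapy
antifibrotic_therapy	therapy
medical_test	medical_procedure
invasive_test	medical_procedure
health_assessment	medical_procedure
medical_diagnosis	medical_procedure
bronchoscopy	medical_procedure
spirometry	medical_test
lung_biopsy	invasive_test
physical_exam	health_assessment
differential_diagnosis	medical_diagnosis
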