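"sample","group","sample_type"
"buccal_gland_1","buccal_gland","biological"
"buccal_gland_2","buccal_gland","biological"
"buccal_gland_3","buccal_gland","biological"
"buccal_gland_4","buccal_gland","biological"
"buccal_gland_5","buccal_gland","biological"
"liver_1","liver","biological"
"liver_2","liver","biological"
"liver_3","liver","biological"
"liver_4","liver","biological"
"liver_5","liver","biological"
"muscle_1","muscle","biological"
"muscle_2","muscle","biological"
"muscle_3","muscle","biological"
"muscle_4","muscle","biological"
"muscle_5","muscle","biological"
"QC_1","QC","qc"
"QC_2","QC","qc"
"QC_3","QC","qc"
"QC_4","QC","qc"
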