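patient_id	tmb_category	msi_status	pdl1_category	er_positive	ar_positive
D1	low	stable	unknown	NA	NA
D2	intermediate	stable	unknown	NA	NA
D3	low	stable	unknown	NA	NA
D4	unknown	msi_high	unknown	NA	NA
D5	unknown	stable	unknown	NA	NA
D6	low	stable	unknown	TRUE	NA
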