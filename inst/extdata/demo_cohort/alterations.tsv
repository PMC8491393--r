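patient_id	report_id	gene	alteration_class	impact_group	pathogenicity
D1	r1	BRAF	mutation	NA	characterized
D1	r1	ERBB2	mutation	NA	characterized
D1	r1	EGFR	mutation	NA	characterized
D1	r1	APC	mutation	NA	characterized
D1	r1	SMAD4	mutation	NA	characterized
D1	r1	MYC	mutation	NA	characterized
D2	r1	PIK3CA	mutation	NA	characterized
D2	r1	FGFR2	mutation	NA	characterized
D3	r1	APC	mutation	NA	characterized
D3	r1	KEAP1	mutation	NA	characterized
D3	r1	STK11	mutation	NA	characterized
D4	r1	ARID1A	mutation	NA	characterized
D4	r1	CTNNB1	mutation	NA	characterized
D4	r1	RB1	mutation	NA	characterized
D4	r1	GNAS	mutation	NA	characterized
D5	r1	BRAF	mutation	NA	characterized
D5	r1	CDH1	mutation	NA	characterized
D6	r1	APC	mutation	NA	characterized
D6	r1	SMAD4	mutation	NA	characterized
D6	r1	MYC	mutation	NA	characterized
D6	r1	RB1	mutation	NA	characterized
D3	r1	TERT	mutation	NA	vus
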