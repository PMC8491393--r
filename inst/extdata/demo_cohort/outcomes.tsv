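patient_id	best_response	sd_duration_months	sd_ongoing	pfs_months	pfs_event	os_months	os_event
D1	PR	NA	FALSE	12.4	TRUE	19.1	TRUE
D2	SD	8.2	FALSE	9.8	TRUE	15.2	TRUE
D3	PD	NA	FALSE	1.9	TRUE	4.6	TRUE
D4	CR	NA	FALSE	21	FALSE	24	FALSE
D5	SD	3.1	TRUE	5.2	FALSE	8.8	FALSE
D6	SD	4.4	FALSE	3.8	TRUE	10.1	TRUE
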