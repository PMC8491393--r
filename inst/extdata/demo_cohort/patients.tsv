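patient_id	tumor_type	age	sex	treated
D1	colorectal	58	male	TRUE
D2	cup	71	female	TRUE
D3	pancreatic	64	female	TRUE
D4	gi_noncolorectal	49	male	TRUE
D5	melanoma	66	male	TRUE
D6	breast	55	female	TRUE
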