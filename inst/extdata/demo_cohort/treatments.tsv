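patient_id	drug
D1	dabrafenib
D1	erlotinib
D1	trastuzumab
D2	pembrolizumab
D2	erdafitinib
D3	gemcitabine
D3	paclitaxel
D4	pembrolizumab
D5	dabrafenib
D5	trametinib
D6	letrozole
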