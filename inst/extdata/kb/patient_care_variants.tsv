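gene	hgvs_c	label
UGT1A1	*28	irinotecan sensitivity
TPMT	c.719A>G	thiopurine sensitivity
TPMT	c.460G>A	thiopurine sensitivity
NUDT15	c.415C>T	thiopurine sensitivity
DPYD	c.1905+1G>A	fluoropyrimidine toxicity
CYP2C19	c.681G>A	clopidogrel metabolism
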