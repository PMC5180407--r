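category	count
all	101
solid	65
hematologic	36
germline_tested	90
solid_germline	57
hematologic_germline	33
cwes_full	60
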