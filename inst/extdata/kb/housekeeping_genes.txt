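# Housekeeping genes for expression normalization (bundled testing subset;
# the production reference uses ~8000 genes)
ACTB
ACTG1
ALDOA
B2M
EEF1A1
EEF2
EIF4A2
ENO1
GAPDH
GPI
GUSB
HMBS
HPRT1
HSP90AB1
IPO8
LDHA
NONO
PGK1
POLR2A
PPIA
PPIH
PSMB2
PSMB4
PUM1
RPL13A
RPL30
RPLP0
RPS17
RPS18
SDHA
TBP
TFRC
TUBB
UBC
UBE2D2
VCP
VPS29
YWHAZ
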