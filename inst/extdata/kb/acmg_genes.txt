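# Secondary-findings gene list (bundled testing subset)
APC
BRCA1
BRCA2
FBN1
KCNQ1
LDLR
MEN1
MLH1
MSH2
MSH6
MYH7
NF2
PMS2
PTEN
RB1
RET
RYR1
SCN5A
SDHB
SDHC
SDHD
STK11
TNNT2
TP53
TSC1
TSC2
VHL
WT1
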