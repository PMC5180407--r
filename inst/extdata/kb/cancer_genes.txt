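# Well-established cancer genes (bundled testing catalog)
ABL1
ALK
APC
ATRX
BRAF
BRCA1
BRCA2
CCND1
CCNE1
CDK2
CDK4
CDKN2A
CEBPA
CTNNB1
DICER1
EGFR
EWSR1
EZH2
FGFR1
FGFR4
FLT3
H3F3A
IDH1
IDH2
JAK1
JAK2
JAK3
KDM6A
KIT
KMT2A
KMT2C
KRAS
MDM2
MYC
MYCN
NF1
NRAS
NT5C2
NTRK3
PDGFRA
PDGFRB
PIK3CA
PTCH1
PTEN
PTPN11
RB1
RELA
RET
SDHC
SETBP1
SMARCA4
SMARCB1
STAT5B
SUFU
TET2
TP53
TSC1
TSC2
VHL
WT1
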