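# Cancer predisposition + pharmacogenomics genes (bundled testing catalog;
# the production list is site-specific and supplied externally)
APC
ATM
BRCA1
BRCA2
C1QA
CDKN2A
CHEK2
CYP2C19
CYP2D6
DICER1
DPYD
G6PD
GATA2
ITK
MLH1
MLL2
MSH2
MSH6
NF1
NF2
NUDT15
PALB2
PMS2
PTCH1
PTEN
RB1
RET
RUNX1
RYR1
SDHB
SDHC
SDHD
SMARCB1
STK11
SUFU
TP53
TPMT
TSC1
TSC2
UGT1A1
VHL
WT1
XIAP
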