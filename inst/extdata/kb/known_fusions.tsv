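gene5	gene3	diagnostic	prognostic	targetable
BCR	ABL1	CML	TRUE	TKI
NUP214	ABL1	ALL	TRUE	TKI
FOXP1	ABL1		TRUE	TKI
ETV6	NTRK3	Infantile fibrosarcoma		TRK/ALK Inhibitor
EWSR1	FLI1	Ewing sarcoma
EWSR1	WT1	DSRCT
PAX3	FOXO1	Alveolar rhabdomyosarcoma	TRUE
PAX7	FOXO1	Alveolar rhabdomyosarcoma	TRUE
ASPSCR1	TFE3	Alveolar soft part sarcoma
CBFB	MYH11	AML	TRUE
CBFA2T3	GLIS2	AMKL	TRUE
C11orf95	RELA	RELA-type supratentorial ependymoma	TRUE
NUP98	NSD1		TRUE	DOT1L Inhibitor
KMT2A	AFF1	ALL	TRUE	DOT1L Inhibitor
EML4	ALK	NSCLC		ALK Inhibitor
TMEM106B	BRAF			MEK Inhibitor
SMARCC2	PDGFRB			TKI
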