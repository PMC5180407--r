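tier	patient_id	diagnosis	disease_group	genes	mutation	therapy	same_patient	therapy_received
1	14-85546	CML	hematologic	BCR-ABL1	Fusion	TKI	FALSE	FALSE
1	13-45348	AML	hematologic	IDH1	c.394C>T (p.R132C)	IDH Inhibitor	TRUE	FALSE
1	14-24794	AML	hematologic	c-KIT;TET2;FLT3	c.2446G>C (p.D816H); c.3663delT (p.C1221Wfs); c.2505T>G (p.D835E)	TKI; Hypomethylating agent; TKI	TRUE	FALSE
1	14-53198	AML	hematologic	TET2	c.1156G>T (p.V386L)	Hypomethylating agent	FALSE	FALSE
1	13-77086	AML	hematologic	c-KIT	c.1965T>G (p.Asn655Lys)	TKI	FALSE	TRUE
2	15-18928	Hepatic rhabdoid tumor	solid	SMARCA4	c.3574C>T (p.R1192C)	EZH2 Inhibitor	FALSE	FALSE
2	14-13487	Osteosarcoma	solid	TSC1	c.2503-1G>C (p.?)	mTOR Inhibitor	FALSE	FALSE
2	14-47205	Nephroblastomatosis	solid	PIK3CA	c.1035T>A (p.N345K)	PI3K/AKT/mTOR Inhibitor	FALSE	FALSE
2	15-40141	Pleomorphic xanthoastrocytoma	solid	TMEM106B-BRAF	Fusion	MEK Inhibitor	FALSE	FALSE
3	15-64793	ALL	hematologic	FOXP1-ABL1	Fusion	TKI	FALSE	TRUE
3	15-26188	ALL	hematologic	NUP214-ABL1	Fusion	TKI	FALSE	TRUE
3	15-79700	ALL	hematologic	NRAS	c.183A>T (p.Q61H)	MEK Inhibitor	FALSE	FALSE
3	14-20062	ALL	hematologic	KRAS	c.183A>T (p.Q61H)	MEK Inhibitor	FALSE	FALSE
3	14-24794	AML	hematologic	NRAS	c.183A>C (p.Q61H)	MEK Inhibitor	TRUE	FALSE
3	15-29224	AML	hematologic	JAK3	c.1718C>T (p.A573V)	JAK Inhibitor	FALSE	FALSE
3	13-45348	AML	hematologic	NRAS	c.38G>C (p.G13A)	MEK Inhibitor	TRUE	FALSE
3	13-95124	AML	hematologic	NRAS;MLL-AFF1 (KMT2A-AFF1)	c.182A>G (p.Q61R); Fusion	MEK Inhibitor; DOT1L Inhibitor	FALSE	FALSE
3	14-45760	AML	hematologic	NRAS	c.38G>A (p.G13D)	MEK Inhibitor	FALSE	FALSE
3	13-50662	AML	hematologic	PTPN11	c.1508G>T (p.G503V)	MEK Inhibitor	FALSE	FALSE
3	14-15491	AML	hematologic	NUP98-NSD1	Fusion	DOT1L Inhibitor	FALSE	FALSE
3	14-27243	Neuroblastoma	solid	NRAS	c.181C>A (p.Q61K)	MEK Inhibitor	FALSE	FALSE
3	14-70449	Rhabdomyosarcoma	solid	NRAS	c.181C>A (p.Q61K)	MEK Inhibitor	FALSE	FALSE
3	14-42817	Neuroblastoma	solid	KRAS	c.34G>T (p.G12C)	MEK Inhibitor	FALSE	FALSE
3	15-11925	Osteosarcoma	solid	MYC	Overexpression	BET Inhibitor	TRUE	FALSE
3	16-74654	Rhabdomyosarcoma	solid	FGFR4	c.1582G>T (p.G528C); c.1648G>C (p.V550L)	FGFR4 Inhibitor	FALSE	FALSE
3	15-23518	Rhabdomyosarcoma	solid	FGFR4	c.1648G>C (p.V550L); c.1949G>T (p.R650L); Overexpression	FGFR4 Inhibitor	FALSE	FALSE
3	14-37237	Glioblastoma multiforme	solid	CDK2	Gain 12q14.1 involving CDK2 (copy number)	CDK4/6 Inhibitor	FALSE	FALSE
3	15-44470	Medulloblastoma	solid	PTCH1;SUFU;ZIC3	Overexpression	SMO Inhibitor	FALSE	FALSE
3	15-10838	Glioma	solid	H3F3A;FGFR1	c.83A>T (p.K28M); c.1731C>A (p.N577K)	HDAC Inhibitor	FALSE	FALSE
3	15-27992	Hepatic rhabdoid tumor	solid	SMARCB1	Homozygous deletion chr22q11.23; loss of expression	EZH2 Inhibitor	FALSE	FALSE
4	15-36388	AML	hematologic	MLL3 (KMT2C)	c.2110G>T (p.E704X)	BET Inhibitor	FALSE	FALSE
4	13-72282	T-ALL	hematologic	KRAS;JAK1;STAT5B	c.40G>A (p.V14I); c.3076A>G (p.K1026E); c.2110A>C (p.I704L)	MEK Inhibitor; JAK Inhibitor; BCL2/BCL-XL Inhibitor	FALSE	FALSE
4	15-66870	Adrenocortical carcinoma	solid	ALK	c.3436C>A (p.Q1146K)	ALK Inhibitor	FALSE	TRUE
5	15-16072	ALL	hematologic	SMARCC2-PDGFRB	Fusion	TKI	FALSE	FALSE
5	14-75899	Neuroblastoma	solid	CDK4;MDM2	Overexpression	NEPENTHE trial	FALSE	FALSE
5	15-11925	Osteosarcoma	solid	MCL1;CCNE1	Overexpression	CDK4/6 Inhibitor	TRUE	FALSE
5	15-35162	Osteosarcoma	solid	CUL4A	Overexpression	NAE Inhibitor	FALSE	FALSE
5	14-71727	Osteosarcoma	solid	RAD51C	c.24T>G (p.F8L)	PARP Inhibitor	FALSE	FALSE
5	15-83826	Osteosarcoma	solid	PDGFRA;KDR (VEGFR2)	Overexpression	MTKI	FALSE	TRUE
5	13-21968	Congenital fibrosarcoma	solid	EML4-NTRK3	Fusion	ALK Inhibitor	FALSE	FALSE
5	14-84044	Inflammatory myofibroblastic tumor	solid	VCAN-IL23R	Fusion	JAK Inhibitor	FALSE	TRUE
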