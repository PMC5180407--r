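section	patient_id	diagnosis	disease_group	alteration	mutation	utility	implication	same_patient
sequence_mutation	15-63375	AML changed to JMML	hematologic	PTPN11;SETBP1	c.181G>T (p.D61Y); c.2602G>A (p.D868N)	diagnostic	JMML	FALSE
sequence_mutation	13-72282	T-ALL	hematologic	STAT5B	c.2110A>C (p.I704L)	diagnostic	Gamma-delta T-cell lymphoma	TRUE
sequence_mutation	15-26188	ALL	hematologic	NT5C2	c.1219G>T (p.D407Y)	pharmacogenomic	Affects therapy	FALSE
sequence_mutation	13-45348	AML	hematologic	IDH1	c.394C>T (p.R132C)	diagnostic	Maffucci syndrome	FALSE
sequence_mutation	14-53198	AML	hematologic	CEBPA	c.939_940insAAG (p.K313_V314insK); c.326_327insC (p.P109fs)	prognostic	Improved prognosis	FALSE
sequence_mutation	15-10838	Glioma	solid	H3F3A	c.83A>T (p.K28M)	prognostic	Poor prognosis	FALSE
sequence_mutation	14-37237	Glioblastoma multiforme	solid	H3F3A	c.83A>T (p.K28M)	prognostic	GBM subgroup K27	FALSE
sequence_mutation	14-35585	Renal cell carcinoma	solid	VHL	c.497T>G (p.V166G)	diagnostic	Von Hippel Lindau	FALSE
sequence_mutation	14-47205	Nephroblastomatosis	solid	PIK3CA	c.1035T>A (p.N345K)	diagnostic	Nephroblastomatosis	FALSE
sequence_mutation	14-78154	Medulloblastoma	solid	KDM6A	c.2989_2990dupAT (p.M997fs)	prognostic	Risk stratification group 4	TRUE
sequence_mutation	14-75899	Neuroblastoma	solid	ATRX	c.5239delA (p.T1747fs)	prognostic	Poor prognosis	FALSE
sequence_mutation	14-10141	Pleuropulmonary blastoma	solid	DICER1	c.5438A>G (p.E1813G)	health_maintenance	DICER syndrome	FALSE
transcriptome_cnv	14-24794	AML	hematologic	CBFB-MYH11	Fusion	prognostic	Low-risk stratification	FALSE
transcriptome_cnv	15-64793	B-ALL	hematologic	FOXP1-ABL1	Fusion	prognostic	High-risk stratification	FALSE
transcriptome_cnv	15-84578	AMKL	hematologic	CBFA2T3-GLIS2	Fusion	diagnostic;prognostic	AMKL; poor prognosis	FALSE
transcriptome_cnv	14-85546	CML	hematologic	BCR-ABL1	Fusion	diagnostic	CML	FALSE
transcriptome_cnv	13-72282	T-ALL	hematologic	Isochromosome 7q	Copy number change	diagnostic	Gamma-delta T-cell lymphoma	TRUE
transcriptome_cnv	15-46387	Rhabdomyosarcoma	solid	PAX7-FOXO1	Fusion	diagnostic;prognostic	Rhabdomyosarcoma; high-risk group	FALSE
transcriptome_cnv	13-81192	Alveolar soft part sarcoma	solid	ASPSCR1-TFE3	Fusion	diagnostic	Alveolar soft part sarcoma	FALSE
transcriptome_cnv	13-65217	Ewing sarcoma	solid	EWSR1-FLI1	Fusion	diagnostic	Ewing sarcoma	FALSE
transcriptome_cnv	15-47087	Ewing sarcoma	solid	EWSR1-FLI1; low expression of PAX8, FHIT, CASP10, CHD2 with high expression of CHD11, FUS, MTA1	Fusion; expression pattern	diagnostic;prognostic	Ewing sarcoma; poor prognosis	FALSE
transcriptome_cnv	13-21968	Undifferentiated sarcoma	solid	EML4-NTRK3	Fusion	diagnostic	Infantile fibrosarcoma	FALSE
transcriptome_cnv	16-88073	Ependymoma	solid	C11orf95-RELA; chromothripsis-like chr11/22	Fusion; copy number change	prognostic;diagnostic	Poor prognosis; RELA-type supratentorial ependymoma	FALSE
transcriptome_cnv	14-27243	Neuroblastoma	solid	MYCN amplified, deletion 1p and 11q, gain 17q; MYCN overexpressed	Copy number change; overexpression	prognostic	Risk-based therapy	FALSE
transcriptome_cnv	14-42817	Neuroblastoma	solid	MYCN non-amplified, no LOH 1p11q; MYCN not overexpressed	Copy number change; no overexpression	prognostic	Risk-based therapy	FALSE
transcriptome_cnv	15-39486	Neuroblastoma	solid	MYCN non-amplified, no LOH 1p11q; MYCN not overexpressed	Copy number change; no overexpression	prognostic	Risk-based therapy	FALSE
transcriptome_cnv	14-44070	Neuroblastoma	solid	MYCN amplified, loss 1p, gain 1q and 17q; MYCN overexpressed	Copy number change; overexpression	prognostic	Risk-based therapy	FALSE
transcriptome_cnv	15-88980	Hepatoblastoma	solid	Amplification 11q13.2 including CCND1; overexpression of CCND1	Copy number change; overexpression	prognostic	Good prognosis	FALSE
transcriptome_cnv	15-49177	Medulloblastoma	solid	IMPG2, GABRA5, LAPTM4B, MAB21L2, NPR3, MFAP4, NRL, ZFPM2, TSHZ3, IGF2BP3, GALNT14, GPR98; loss 10q22.2-10qter involving PTEN and SUFU, loss 17p, gain 17q	Overexpression; copy number change	prognostic	Risk stratification subgroup 3/4	FALSE
transcriptome_cnv	15-70532	Ependymoma	solid	Gain 1q, loss 6q	Copy number change	prognostic	Poor prognosis	FALSE
transcriptome_cnv	14-78154	Medulloblastoma	solid	KCNA1, RBM24, KLHL13, EN2, SNCAIP, PDE1C, GRM8, KCNIP4, EXPH5, UNC5D, NID2, ST18, GPR12, SH3GL3; i17q	Overexpression; copy number change	prognostic	Risk stratification subgroup 4	TRUE
transcriptome_cnv	15-40141	Pleomorphic xanthoastrocytoma	solid	Gain chromosome 7, LOH 9p	Copy number change	diagnostic	Pleomorphic xanthoastrocytoma	FALSE
transcriptome_cnv	15-97336	Small round blue cell tumor	solid	EWSR1-WT1	Fusion	diagnostic	DSRCT	FALSE
transcriptome_cnv	15-34296	Ependymoma	solid	TNC, CALB1, PLAG1, ALDH1L1, RELN	Overexpression	prognostic	Risk stratification group A, poor prognosis	FALSE
transcriptome_cnv	15-80972	ATRT	solid	LOH 22q11.21qter including SMARCB1; ASCL1	Copy number change; overexpression	diagnostic;prognostic	ATRT; improved prognosis	FALSE
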