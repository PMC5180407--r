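gene	drug	approval_status	pediatric_dosing	evidence_class	tumor_types	pathway
ABL1	dasatinib	approved	yes	clinical	CML;Ph-positive ALL	ABL kinase
KIT	imatinib	approved	yes	clinical	AML;GIST	KIT kinase
IDH1	ivosidenib	approved	yes	clinical	AML	IDH
TET2	azacitidine	approved	yes	clinical	AML;MDS	DNA methylation
FLT3	sorafenib	approved	yes	clinical	AML	FLT3 kinase
SMARCA4	tazemetostat	experimental	yes	clinical	Malignant rhabdoid tumor	SWI/SNF-EZH2
TSC1	everolimus	approved	yes	clinical	Subependymal giant cell astrocytoma	mTOR
PIK3CA	alpelisib	experimental	yes	clinical	Breast carcinoma	PI3K/AKT/mTOR
BRAF	trametinib	approved	yes	clinical	Melanoma;Low-grade glioma	MAPK
NRAS	trametinib	approved	yes	preclinical	ALL;AML;Neuroblastoma;Rhabdomyosarcoma	MAPK
KRAS	trametinib	approved	yes	preclinical	ALL;AML;Neuroblastoma	MAPK
PTPN11	trametinib	approved	yes	preclinical	AML	MAPK
JAK3	ruxolitinib	approved	yes	preclinical	AML	JAK/STAT
MYC	JQ1	experimental	yes	preclinical	Osteosarcoma	BET bromodomain
FGFR4	ponatinib	experimental	yes	preclinical	Rhabdomyosarcoma	FGFR kinase
CDK2	palbociclib	approved	yes	preclinical	Glioblastoma multiforme	Cell cycle
PTCH1	vismodegib	approved	yes	preclinical	Medulloblastoma	Hedgehog
SUFU	vismodegib	approved	yes	preclinical	Medulloblastoma	Hedgehog
H3F3A	panobinostat	experimental	yes	preclinical	Glioma	HDAC
SMARCB1	tazemetostat	experimental	yes	preclinical	Hepatic rhabdoid tumor;ATRT	SWI/SNF-EZH2
KMT2C	JQ1	experimental	yes	preclinical	Breast carcinoma	BET bromodomain
JAK1	ruxolitinib	approved	yes	preclinical	Myelofibrosis	JAK/STAT
STAT5B	navitoclax	experimental	yes	preclinical	Hepatosplenic T-cell lymphoma	BCL2/BCL-XL
ALK	crizotinib	approved	yes	preclinical	Neuroblastoma	ALK kinase
NTRK3	crizotinib	approved	yes	preclinical	Infantile fibrosarcoma	TRK kinase
ERBB2	trastuzumab	approved	no	clinical	Breast carcinoma	HER2
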