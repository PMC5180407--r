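section	patient_id	diagnosis	disease_group	gene	hgvs_c	hgvs_p	mutation_type	utility	implication	previously_known	same_patient
hematologic	14-19751	HLH	hematologic	MLL2	c.11640_11640delG; c.15631G>A	p.M3881Cfs*9 (de novo); p.E5211K	compound heterozygous, frameshift	diagnostic	Kabuki syndrome; transplantation withheld	FALSE	FALSE
hematologic	15-90485	HLH	hematologic	C1QA	c.622C>T	p.Gln208Ter	homozygous, nonsense	diagnostic	C1Q deficiency	FALSE	FALSE
hematologic	15-33031	MDS	hematologic	GATA2	c.16delG	p.(E6fs)	heterozygous, frameshift	other_impact;health_maintenance	Increased risk for developing AML and MDS; supports transplant recommendation	FALSE	FALSE
hematologic	14-92247	ALL	hematologic	PMS2	c.1376C>G	p.S459X	homozygous, missense	diagnostic;health_maintenance	Constitutional mismatch repair deficiency syndrome; Lynch syndrome (parents)	FALSE	FALSE
hematologic	15-46877	HLH	hematologic	XIAP	c.1328G>C	p.R443P	missense	diagnostic	X-linked lymphoproliferative syndrome 2; transplantation recommended	FALSE	FALSE
hematologic	14-19750	AML	hematologic	RUNX1	c.806-2A>G	r.Spl?	heterozygous splice site	diagnostic	Familial platelet disorder; transplant donor changed	FALSE	FALSE
solid	14-56374	Hepatoblastoma	solid	APC	c.3340C>T	p.R1114	nonsense	diagnostic;health_maintenance	Familial adenomatous polyposis	TRUE	FALSE
solid	15-33544	Poorly differentiated carcinoma	solid	APC	c.4660_4661insA	p.E1554fs	frameshift (de novo)	diagnostic;health_maintenance	Gardner syndrome; familial adenomatous polyposis	FALSE	FALSE
solid	15-35162	Osteosarcoma	solid	RB1	c.1216-3A>G	p.?	splice site	health_maintenance	Increased risk for developing other cancers	TRUE	FALSE
solid	15-44470	Medulloblastoma	solid	ATM	c.566G>A; c.8266A>T	p.R189K; p.K2756*	missense, nonsense	health_maintenance	Increased risk for developing other cancers	FALSE	FALSE
solid	15-78886	Pineoblastoma	solid	UGT1A1	*28 allele ((TA)7TAA)		homozygous	pharmacogenomic	Drug sensitivity	FALSE	TRUE
solid	15-78886	Pineoblastoma	solid	DICER1	c.4807dupC	p.L1603Pfs	frameshift	health_maintenance	Risk of ovarian Sertoli-Leydig cell tumor	FALSE	TRUE
solid	15-17264	Hepatocellular carcinoma	solid	UGT1A1	*28 allele		heterozygous	pharmacogenomic	Drug sensitivity	FALSE	FALSE
acmg	15-29224	AML	hematologic	TP53	c.644G>A	p.S215N	missense	other_impact;health_maintenance	Explains lack of response to conventional therapy; increased cancer risk	FALSE	FALSE
acmg	14-59462	Nested stromal epithelial tumor of the liver	solid	BRCA1	c.68_69delAG	p.Glu23Valfs	frameshift	health_maintenance	Breast cancer	FALSE	FALSE
acmg	16-88073	Ependymoma	solid	BRCA1	c.5587_5594delGTAGCACT	p.V1863Lfs*35	frameshift	health_maintenance	Breast cancer	FALSE	FALSE
acmg	14-75899	Neuroblastoma	solid	RYR1	c.6838G>A	p.V2280I	missense	health_maintenance	Malignant hyperthermia	FALSE	FALSE
acmg	14-13487	Osteosarcoma	solid	TNNT2	c.422G>A	p.Arg141Gln	heterozygous	health_maintenance	Dilated cardiomyopathy	FALSE	FALSE
acmg	15-34296	Ependymoma	solid	VHL	c.539T>C	p.I180T	missense	health_maintenance	Von Hippel Lindau syndrome	FALSE	FALSE
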