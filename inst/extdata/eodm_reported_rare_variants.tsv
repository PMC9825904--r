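gene_list	gene	hgvs_c	hgvs_p	variant_type_reported	phylop	cadd_phred	grantham	clinvar	n_patients	maf_cohort_pct	maf_gnomad_pct
lipid,mouse_model	LDLR	c.47T>C	p.Leu16Pro	Missense	3.1	24.2	98	VUS	2	2.04	NA
lipid,mouse_model	APOB	c.3449T>A	p.Met1150Lys	Missense	3.3	23.4	95	VUS	1	1.02	0.002
lipid,mouse_model	APOB	c.2437-2A>G	NA	Splice-site	2.6	25.4	0	VUS	1	1.02	NA
complement,mouse_model	C3	c.4992A>G	p.*1664Trpext*58	Stop-loss	4.6	14.4	1000	NA	1	1.02	NA
complement,mouse_model	C3	c.1661A>G	p.Asp554Gly	Missense	7.3	25.1	94	NA	1	1.02	NA
complement,mouse_model	CFH	c.350+6T>G	NA	Splice-site	2.7	20.4	0	Pathogenic	1	1.02	NA
mouse_model	CX3CR1	c.74A>G	p.Asp25Gly	Missense	5.4	22.0	94	Likely benign	1	1.02	0.16
mouse_model	CD36	c.1144C>T	p.Gln382*	Nonsense	0.6	47.0	1000	VUS	1	1.02	0.01
lipid	MTTP	c.103_106del	p.Lys35Valfs*20	Frameshift	-0.2	9.9	1000	NA	1	1.02	NA
lipid	CYP4V2	c.169T>C	p.Tyr57His	Missense	4.6	23.9	83	VUS	1	1.02	0.02
lipid	ABCA1	c.3542C>T	p.Ser1181Phe	Missense	9.5	23.9	155	VUS	1	1.02	0.14
lipid	ACAT1	c.1217A>G	p.Glu406Gly	Missense	9.0	32.0	98	VUS	2	2.04	0.03
complement	CFHR2	c.595G>T	p.Glu199*	Nonsense	-1.4	35.0	1000	Benign	1	1.02	0.75
complement	C8A	c.454del	p.Ala152Glnfs*8	Frameshift	-100.0	14.7	0	NA	1	1.02	0.0004
complement	C8B	c.865A>T	p.Lys289*	Nonsense	1.2	39.0	1000	NA	1	1.02	NA
complement	C9	c.162C>A	p.Cys54*	Nonsense	1.3	35.0	1000	Pathogenic/likely pathogenic	1	1.02	0.09
complement	CSMD1	c.8687C>T	p.Thr2896Met	Missense	5.3	22.5	81	NA	1	1.02	0.004
complement	CSMD1	c.554G>T	p.Cys185Phe	Missense	7.6	26.2	205	NA	1	1.02	NA
complement	CSMD2	c.6073C>T	p.Arg2025Trp	Missense	5.2	32.0	101	NA	1	1.02	0.002
complement	CSMD2	c.3839C>T	p.Ser1280Leu	Missense	3.5	21.5	145	NA	1	1.02	0.005
complement	CSMD2	c.3520G>A	p.Gly1174Arg	Missense	4.0	24.5	125	NA	1	1.02	0.10
complement	CSMD2	c.1394G>A	p.Gly465Asp	Missense	7.5	26.8	94	NA	1	1.02	0.05
complement	FCN1	c.868C>T	p.Arg290*	Nonsense	-2.5	0.0	1000	NA	1	1.02	NA
complement	MASP1	c.1770del	p.Lys591Serfs*11	Frameshift	-100.0	10.1	0	NA	1	1.02	0.02
complement	MASP2	c.467G>A	p.Cys156Tyr	Missense	7.6	26.5	194	Benign/likely benign	1	1.02	0.59
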