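variant_id	gene	hgvs	rsid	chrom	pos	ref	alt	category	acmg_class	phenotype_class	allele_class	modifier_effect	klf1_zinc_finger	screening_relevant	source
HBB_CD41-42	HBB	HBB:c.126_129delCTTT	.	11	5248050	CTTT	-	disease_causing	pathogenic	thalassemia	beta0	none	false	true	common Chinese beta0 allele
HBB_CD17	HBB	HBB:c.52A>T	.	11	5248158	A	T	disease_causing	pathogenic	thalassemia	beta0	none	false	true	common Chinese beta0 allele
HBB_IVS-II-654	HBB	HBB:c.316-197C>T	.	11	5247153	C	T	disease_causing	pathogenic	thalassemia	beta_plus	none	false	true	common Chinese beta+ allele
HBB_-28	HBB	HBB:c.-78A>G	.	11	5248280	A	G	disease_causing	pathogenic	thalassemia	beta_plus	none	false	true	promoter beta+ allele
HbE	HBB	HBB:c.79G>A	rs33950507	11	5248173	G	A	disease_causing	pathogenic	Hb_variant	betaE	none	false	true	Hb E
HbS	HBB	HBB:c.20A>T	rs334	11	5248232	A	T	disease_causing	pathogenic	Hb_variant	betaS	none	false	true	Hb S
HbMidnapore	HBB	HBB:c.161C>T	.	11	5248114	C	T	disease_causing	likely_pathogenic	Hb_variant	none	none	false	true	rare clinically significant Hb variant
HbJ-Bangkok	HBB	HBB:c.170G>A	.	11	5248105	G	A	disease_causing	benign	Hb_variant	none	none	false	false	benign Hb variant
HBD_delta-thal	HBD	HBD:c.-77T>C	.	11	5255500	T	C	disease_causing	likely_pathogenic	thalassemia	none	none	false	false	delta-thalassemia allele
HbF-Jiangsu	HBG1	HBG1:c.403G>A	.	11	5270200	G	A	disease_causing	likely_benign	Hb_variant	none	none	false	false	abnormal fetal hemoglobin variant
HPFH_SEA	HBB		.	.	.	.	SEA-HPFH	disease_causing	likely_pathogenic	HPFH	hpfh_del	none	false	false	deletional HPFH
alpha_SEA	HBA2		.	.	.	.	--SEA	disease_causing	pathogenic	thalassemia	0	none	false	true	Southeast Asian double-gene deletion
alpha_THAI	HBA2		.	.	.	.	--THAI	disease_causing	pathogenic	thalassemia	0	none	false	true	Thai double-gene deletion
alpha_FIL	HBA2		.	.	.	.	--FIL	disease_causing	pathogenic	thalassemia	0	none	false	true	Filipino double-gene deletion
alpha_3.7	HBA2		.	.	.	.	-a3.7	disease_causing	pathogenic	thalassemia	1	none	false	true	rightward single-gene deletion
alpha_4.2	HBA2		.	.	.	.	-a4.2	disease_causing	pathogenic	thalassemia	1	none	false	true	leftward single-gene deletion
HbCS	HBA2	HBA2:c.427T>C	.	16	223704	T	aCSa	disease_causing	pathogenic	thalassemia	1	none	false	true	Hb Constant Spring (nondeletional)
HbQS	HBA2	HBA2:c.377T>C	.	16	223654	T	aQSa	disease_causing	pathogenic	thalassemia	1	none	false	true	Hb Quong Sze (nondeletional)
alpha_aaa	HBA1		.	.	.	.	aaa	modifier	likely_benign	uncertain	3	severity_modifier	false	false	alpha-globin triplication
alpha_aaaa	HBA1		.	.	.	.	aaaa	modifier	likely_benign	uncertain	4	severity_modifier	false	false	alpha-globin quadruplication
KLF1_zf_R328H	KLF1	KLF1:c.983G>A	.	19	12995430	C	T	modifier	likely_pathogenic	uncertain	none	severity_modifier	true	true	zinc-finger domain variant
KLF1_zf_G176fs	KLF1	KLF1:c.525_526insCGGCGCC	.	19	12997350	-	CGGCGCC	modifier	likely_pathogenic	uncertain	none	severity_modifier	true	true	frameshift destroying the zinc-finger domain
KLF1_promoter	KLF1	KLF1:c.-154C>T	.	19	12998000	G	A	modifier	uncertain_significance	uncertain	none	none	false	false	promoter variant, unclear modification
GATA1_mod	GATA1	GATA1:c.622G>A	.	X	48650500	G	A	modifier	uncertain_significance	uncertain	none	severity_modifier	false	false	erythroid transcription factor variant
rs61749494	BCL11A	.	rs61749494	2	60689441	T	C	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs10189857	BCL11A	.	rs10189857	2	60713235	A	G	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs6545816	BCL11A	.	rs6545816	2	60714861	A	C	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs1427407	BCL11A	.	rs1427407	2	60718043	T	G	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs7599488	BCL11A	.	rs7599488	2	60718347	C	T	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs766432	BCL11A	.	rs766432	2	60719970	C	A	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs4671393	BCL11A	.	rs4671393	2	60720951	A	G	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs375867652	HMIP	.	rs375867652	6	135419038	C	-	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs11759553	HMIP	.	rs11759553	6	135422296	A	T	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs35959442	HMIP	.	rs35959442	6	135424179	C	G	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs4895440	HMIP	.	rs4895440	6	135426558	A	T	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs4895441	HMIP	.	rs4895441	6	135426573	A	G	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs9402686	HMIP	.	rs9402686	6	135427817	G	A	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs9494142	HMIP	.	rs9494142	6	135431640	T	C	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs6934903	HMIP	.	rs6934903	6	135451564	T	A	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs78981054	HBG1	.	rs78981054	11	5270347	AAAG	-	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs34879481	HBG2	.	rs34879481	11	5274452	-	T	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs28379094	HBG1	.	rs28379094	11	5269806	C	T	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs2187608	HBG1	.	rs2187608	11	5269931	G	C	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs7482933	HBG1	.	rs7482933	11	5270002	G	A	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs2855039	HBG1	.	rs2855039	11	5271671	C	T	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs2855038	HBG1	.	rs2855038	11	5272154	T	C	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs2855036	HBG1	.	rs2855036	11	5272682	C	T	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs2070972	HBG2	.	rs2070972	11	5274717	A	C	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs11036474	HBG2	.	rs11036474	11	5275178	T	C	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs11036475	HBG2	.	rs11036475	11	5275240	G	A	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs11036476	HBG2	.	rs11036476	11	5275343	C	T	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs2070973	HBG2	.	rs2070973	11	5275407	T	C	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs7482144	HBG2	.	rs7482144	11	5276169	G	A	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs2855123	HBG2	.	rs2855123	11	5277078	A	T	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs2855122	HBG2	.	rs2855122	11	5277236	C	T	modifier	benign	uncertain	none	decreases_HbF	false	false	curated modifier scan
rs2855121	HBG2	.	rs2855121	11	5277291	C	T	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs34306743	HBG1	.	rs34306743	11	5272553	-	A	modifier	benign	uncertain	none	elevates_HbF	false	false	curated modifier scan
rs483352838	KLF1	.	rs483352838	19	12996518	-	GGCGCCG	modifier	uncertain_significance	uncertain	none	elevates_HbF	false	false	curated modifier scan
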