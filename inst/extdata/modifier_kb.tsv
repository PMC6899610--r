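variant_id	gene	hgvs	rsid	chrom	pos	ref	alt	category	acmg_class	phenotype_class	allele_class	modifier_effect	klf1_zinc_finger	screening_relevant	source
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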