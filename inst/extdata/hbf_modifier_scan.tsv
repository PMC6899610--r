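SNPs	Locus	Location	Nucleotide_change	Frequency	Modification	P_value	HbF_carriers	HbF_noncarriers
rs61749494	BCL11A	2:60689441	T>C	0.251	Elevated HbF	4.24e-06	18.6820	11.6439
rs10189857	BCL11A	2:60713235	A>G	0.9235	Decreased HbF	1.64e-06	12.8591	20.0668
rs6545816	BCL11A	2:60714861	A>C	0.9216	Decreased HbF	3.24e-06	12.8711	19.7456
rs1427407	BCL11A	2:60718043	T>G	0.9275	Decreased HbF	1.95e-06	12.9450	19.3588
rs7599488	BCL11A	2:60718347	C>T	0.9235	Decreased HbF	2.77e-06	12.8542	20.1268
rs766432	BCL11A	2:60719970	C>A	0.9255	Decreased HbF	1.65e-05	13.0060	18.4325
rs4671393	BCL11A	2:60720951	A>G	0.9275	Decreased HbF	3.43e-06	12.9880	18.8090
rs375867652	HMIP	6:135419038	delC	0.3275	Elevated HbF	1.59e-04	17.3037	11.5147
rs11759553	HMIP	6:135422296	A>T	0.3451	Elevated HbF	5.61e-05	17.2904	11.3657
rs35959442	HMIP	6:135424179	C>G	0.349	Elevated HbF	6.06e-05	17.2321	11.3613
rs4895440	HMIP	6:135426558	A>T	0.349	Elevated HbF	6.06e-05	17.2321	11.3613
rs4895441	HMIP	6:135426573	A>G	0.349	Elevated HbF	6.06e-05	17.2321	11.3613
rs9402686	HMIP	6:135427817	G>A	0.351	Elevated HbF	6.06e-05	17.1452	11.3906
rs9494142	HMIP	6:135431640	T>C	0.3627	Elevated HbF	5.17e-05	16.9296	11.4070
rs6934903	HMIP	6:135451564	T>A	0.3373	Elevated HbF	9.34e-05	16.6348	11.7694
rs78981054	HBG1	11:5270347	delAAAG	0.9863	Decreased HbF	4.66e-08	13.1293	33.6006
rs34879481	HBG2	11:5274452	insT	0.1392	Elevated HbF	4.19e-12	23.3682	11.7998
rs28379094	HBG1	11:5269806	C>T	0.9843	Decreased HbF	1.65e-12	13.0232	37.7005
rs2187608	HBG1	11:5269931	G>C	0.1373	Elevated HbF	1.41e-12	23.3314	11.832
rs7482933	HBG1	11:5270002	G>A	0.8588	Decreased HbF	1.15e-09	11.8743	22.7546
rs2855039	HBG1	11:5271671	C>T	0.1373	Elevated HbF	6.93e-12	23.3314	11.832
rs2855038	HBG1	11:5272154	T>C	0.9863	Decreased HbF	4.46e-11	13.1293	33.6006
rs2855036	HBG1	11:5272682	C>T	0.1373	Elevated HbF	1.30e-11	23.3314	11.832
rs2070972	HBG2	11:5274717	A>C	0.9843	Decreased HbF	5.86e-11	13.1411	30.303
rs11036474	HBG2	11:5275178	T>C	0.1412	Elevated HbF	7.90e-12	23.3499	11.7764
rs11036475	HBG2	11:5275240	G>A	0.9863	Decreased HbF	2.06e-11	13.1293	33.6006
rs11036476	HBG2	11:5275343	C>T	0.9863	Decreased HbF	9.69e-11	13.1293	33.6006
rs2070973	HBG2	11:5275407	T>C	0.9863	Decreased HbF	9.69e-11	13.1293	33.6006
rs7482144	HBG2	11:5276169	G>A	0.1412	Elevated HbF	1.81e-11	23.3499	11.7764
rs2855123	HBG2	11:5277078	A>T	0.9863	Decreased HbF	3.92e-10	13.1293	33.6006
rs2855122	HBG2	11:5277236	C>T	0.9863	Decreased HbF	1.20e-11	13.1293	33.6006
rs2855121	HBG2	11:5277291	C>T	0.1392	Elevated HbF	7.90e-12	23.3682	11.7998
rs34306743	HBG1	11:5272553	insA	0.1373	Elevated HbF	1.30e-11	23.3314	11.832
rs483352838	KLF1	19:12996518	insGGCGCCG	0.0137	Elevated HbF	1.93e-06	39.2343	13.0509
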