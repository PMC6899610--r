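gene	category	phenotype_class	count
HBB	disease_causing	Hb_variant	28
HBB	disease_causing	thalassemia	92
HBB	disease_causing	HPFH	2
HBB	disease_causing	uncertain	2
HBA1	disease_causing	Hb_variant	6
HBA1	disease_causing	thalassemia	27
HBA1	disease_causing	HPFH	0
HBA1	disease_causing	uncertain	11
HBA2	disease_causing	Hb_variant	13
HBA2	disease_causing	thalassemia	33
HBA2	disease_causing	HPFH	0
HBA2	disease_causing	uncertain	8
HBD	disease_causing	Hb_variant	4
HBD	disease_causing	thalassemia	17
HBD	disease_causing	HPFH	2
HBD	disease_causing	uncertain	2
HBG1	disease_causing	Hb_variant	2
HBG1	disease_causing	thalassemia	0
HBG1	disease_causing	HPFH	1
HBG1	disease_causing	uncertain	8
HBG2	disease_causing	Hb_variant	2
HBG2	disease_causing	thalassemia	0
HBG2	disease_causing	HPFH	0
HBG2	disease_causing	uncertain	5
.	modifier	.	106
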