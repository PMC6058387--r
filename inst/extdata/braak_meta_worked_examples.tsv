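rank	p_meta	p_neuron	p_glia	probe_id	chromosome	position	gene	region	fdr
1	1.50E-13	1.15E-06	3.83E-09	cg06549928	1	89990868	LRRC8B	5UTR	7.17624E-08
2	6.43E-11	4.64E-06	4.98E-07	cg21913630	7	128828599	SMO	TSS200	1.53811E-05
3	2.05E-10	3.04E-05	2.54E-07	cg16562251	1	166845621	TADA1	1stExon	3.26918E-05
4	2.90E-10	1.15E-05	9.63E-07	cg08738571	12	32655192	FGD4	1stExon	3.45416E-05
5	3.61E-10	9.00E-06	1.54E-06	cg22140756	2	177895827			3.45416E-05
6	4.81E-10	7.42E-06	2.52E-06	cg04913265	11	133939627	JAM3	Body	3.8353E-05
7	8.78E-10	1.69E-05	2.07E-06	cg20693608	4	113152836	AP1AR	TSS200	6.0007E-05
8	1.57E-09	7.82E-06	8.20E-06	cg24449302	15	66679100	MAP2K1	TSS200	7.02674E-05
9	1.60E-09	7.69E-06	8.51E-06	cg13172549	7	27153636	HOXA3	5UTR	7.02674E-05
10	1.61E-09	2.63E-06	2.50E-05	cg04547723	14	75421960	PGF	5UTR	7.02674E-05
11	1.67E-09	1.49E-05	4.58E-06	cg07835289	1	236030215	LYST	5UTR	7.02674E-05
15	2.27E-09	0.00021772	4.33E-07	cg11817993	14	92572978	ATXN3	TSS200	7.02674E-05
21	5.19E-09	3.14E-05	7.12E-06	cg02037503	14	23540729	ACIN1	1stExon	0.000118237
27	1.04E-08	7.43E-05	6.24E-06	cg03040740	13	99084682	FARP1	Body	0.000184279
32	1.44E-08	0.00087784	7.40E-07	cg13859639	11	2846716	KCNQ1	Body	0.000215287
38	2.41E-08	0.00041341	2.70E-06	cg03907612	6	41703314	TFEB	5UTR	0.000303416
39	2.60E-08	7.11E-05	1.70E-05	cg16568373	17	4853368	ENO3	TSS1500	0.000318944
48	3.48E-08	2.84E-05	5.76E-05	cg05884192	14	52515736	NID2	Body	0.000334891
53	3.75E-08	0.00012506	1.42E-05	cg08883485	1	201619787	NAV1	Body	0.000334891
58	4.55E-08	4.14E-05	5.24E-05	cg23712970	14	23540735	ACIN1	1stExon	0.000374624
74	6.71E-08	1.05E-05	0.0003106	cg08843538	2	210288784	MAP2	1stExon	0.000429299
76	6.94E-08	4.79E-05	7.07E-05	cg04542489	14	23775746	BCL2L2	TSS1500	0.00043306
102	1.24E-07	4.82E-05	0.00012891	cg06355720	1	153333350	S100A9	3UTR	0.000581604
103	1.27E-07	5.37E-05	0.00011905	cg26327118	6	39693366	KIF6	TSS200	0.000589892
104	1.31E-07	1.08E-05	0.00061189	cg16258854	2	20648194	RHOB	1stExon	0.000595763
111	1.41E-07	0.00052315	1.36E-05	cg08866780	21	27543523	APP	TSS1500	0.000604315
112	1.42E-07	0.01466411	4.90E-07	cg03613822	17	7115140	DLG4	Body	0.000604315
126	1.71E-07	5.41E-06	0.00161641	cg06291595	14	74960292	NPC2	TSS1500	0.000646609
131	1.86E-07	0.01071281	8.90E-07	cg04153489	8	41655983	ANK1	TSS1500	0.000679278
133	1.99E-07	2.07E-05	0.00049571	cg19447671	2	176032513	ATF2	5UTR	0.000715825
134	2.04E-07	0.00058734	1.79E-05	cg10313337	16	68823690	CDH1	Body	0.000728335
141	2.18E-07	0.00020684	5.47E-05	cg01015899	12	120663812	PXN	5UTR	0.000737839
152	2.41E-07	2.45E-05	0.00051347	cg27212541	3	49507385	DAG1	TSS200	0.00075801
161	2.68E-07	0.00027187	5.17E-05	cg07745886	8	42150794	IKBKB	Body	0.000796369
199	4.19E-07	0.00095868	2.35E-05	cg01231165	2	9695142	ADAM17	Body	0.001001966
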