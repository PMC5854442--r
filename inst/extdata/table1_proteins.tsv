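row	protein	species	copy_number	kd_pm_lo_uM	kd_pm_hi_uM	kd_censored_above_uM	kd_estimated_values_uM	kd_pm_cargo_uM	lipid_binding	affinity_basis	provenance
1	OSH2	yeast	850	1	1.5	FALSE	NA	NA	TRUE	measured	PLI PMID:11238399; affinity same ref
2	SWH1	yeast	505	3.5	6.2	FALSE	NA	NA	TRUE	measured	PLI PMID:21119626; affinity same ref
3	KES1	yeast	21166	0.055	2.2	FALSE	NA	NA	TRUE	measured	PLI PMID:22162133,11916983; affinity same
4	VPS17	yeast	1077	100	NA	TRUE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
5	SNX4	yeast	1483	100	NA	TRUE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
6	SNX41	yeast	367	100	NA	TRUE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
7	VPS5	yeast	1326	100	NA	TRUE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
8	ATG20	yeast	519	100	NA	TRUE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
9	BOI2	yeast	567	6.6	19.5	FALSE	NA	NA	TRUE	measured	PLI PMID:15023338; affinity same ref
10	CLA4	yeast	397	20.2	100	FALSE	NA	NA	TRUE	measured	PLI PMID:15023338; affinity same ref
11	SKM1	yeast	16	3.9	6.4	FALSE	NA	NA	TRUE	measured	PLI PMID:15023338; affinity same ref
12	BEM1	yeast	1037	100	NA	TRUE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
13	BOI1	yeast	399	20	20	FALSE	NA	NA	TRUE	measured	PLI PMID:15023338; affinity same ref
14	VAM7	yeast	210	2	3	FALSE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
15	SNX3	yeast	5092	2	3	FALSE	NA	NA	TRUE	measured	PLI PMID:11557775; affinity same ref
16	SLA2	yeast	3904	0.27	3.4	FALSE	NA	NA	TRUE	homology	PLI PMID:15574875; affinity homology AP180 PMID:12740367
17	SYP1	yeast	2467	NA	NA	FALSE	0.1;10;100	NA	TRUE	estimated	PLI PMID:19713939,1321812; affinity estimated
18	ENT1	yeast	1750	0.08	0.08	FALSE	NA	NA	TRUE	homology	PLI PMID:22193158,10449404; affinity homology EPN1 PMID:17825837
19	ENT2	yeast	1325	0.08	0.08	FALSE	NA	NA	TRUE	homology	PLI PMID:22193158,10449404; affinity homology EPN1 PMID:17825837
20	YAP1802	yeast	264	0.27	3.4	FALSE	NA	NA	TRUE	homology	PLI PMID:22193158,21119626; affinity homology AP180 PMID:12740367
21	SLA1	yeast	2964	NA	NA	FALSE	NA	NA	FALSE	none	scaffold; no lipid binding
22	EDE1	yeast	5964	NA	NA	FALSE	NA	NA	FALSE	none	scaffold; no lipid binding
23	FCHO1	human	3706	NA	NA	FALSE	0.1;10;100	NA	TRUE	estimated	PLI PMID:22484487; affinity estimated
24	AP-2	human	244537	2.86	2.86	FALSE	NA	0.072	TRUE	measured	PLI PMID:15916959; affinity same ref; copy number AP2A1 gene
25	EPN1	human	570949	0.08	0.08	FALSE	NA	NA	TRUE	measured	PLI PMID:17825837; affinity same ref
26	PICALM	human	358673	2.7	3.4	FALSE	NA	NA	TRUE	homology	PLI PMID:25090048; affinity homology AP180 PMID:12740367
27	DAB2	human	1078162	0.08	0.08	FALSE	NA	NA	TRUE	homology	PLI PMID:12234931; affinity homology EPN1 PMID:17825837
28	FCHO2	human	36302	NA	NA	FALSE	0.1;10;100	NA	TRUE	estimated	PLI PMID:20448150; affinity estimated
29	SNAP91/AP180	human	21716	0.27	3.4	FALSE	NA	NA	TRUE	measured	PLI PMID:12740367; copies scaled from ppm PMID:24920484 via AP-2 count PMID:26496610
30	LDLRAP1/ARH	human	1048	0.08	0.08	FALSE	NA	NA	TRUE	homology	PLI PMID:12234931; affinity homology EPN1 PMID:17825837
31	HIP1	human	13771	0.27	3.4	FALSE	NA	NA	TRUE	homology	PLI PMID:14732715; affinity homology AP180 PMID:12740367
32	HIP1R	human	24161	0.27	3.4	FALSE	NA	NA	TRUE	homology	PLI PMID:14732715; affinity homology AP180 PMID:12740367
33	AMPH	human	89536	0.1	0.1	FALSE	NA	NA	TRUE	measured	PLI PMID:22888025; affinity same ref
34	SH3GL2/Endophilin	human	55621	0.03	0.03	FALSE	NA	NA	TRUE	measured	PLI PMID:22888025; affinity same ref
35	EPS15	human	91354	NA	NA	FALSE	NA	NA	FALSE	none	scaffold; no lipid binding
36	ITSN1	human	20184	NA	NA	FALSE	NA	NA	FALSE	none	scaffold; no lipid binding
37	CLTC	human	1495814	NA	NA	FALSE	NA	NA	FALSE	none	no lipid binding; trimer simulations divide heavy-chain copies by 3
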