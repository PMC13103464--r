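number	region	abbreviation	lobe	lobe_abbr
1	Bankssts L	L.BSTS	Temporal	T
2	Bankssts R	R.BSTS	Temporal	T
3	Caudal middle frontal L	L.CMF	Frontal	F
4	Caudal middle frontal R	R.CMF	Frontal	F
5	Cuneus L	L.CUN	Occipital	O
6	Cuneus R	R.CUN	Occipital	O
7	Frontal pole L	L.FP	Prefrontal	PF
8	Frontal pole R	R.FP	Prefrontal	PF
9	Inferior parietal L	L.IPL	Parietal	P
10	Inferior parietal R	R.IPL	Parietal	P
11	Insula L	L.INS	Temporal	T
12	Insula R	R.INS	Temporal	T
13	Lateral occipital L	L.LOG	Occipital	O
14	Lateral occipital R	R.LOG	Occipital	O
15	Medial orbitofrontal L	L.MOF	Prefrontal	PF
16	Medial orbitofrontal R	R.MOF	Prefrontal	PF
17	Middle temporal L	L.MTG	Temporal	T
18	Middle temporal R	R.MTG	Temporal	T
19	Paracentral L	L.PCL	Central	C
20	Paracentral R	R.PCL	Central	C
21	Pars opercularis L	L.POG	Frontal	F
22	Pars opercularis R	R.POG	Frontal	F
23	Pars orbitalis L	L.PO	Prefrontal	PF
24	Pars orbitalis R	R.PO	Prefrontal	PF
25	Pars triangularis L	L.PTRI	Frontal	F
26	Pars triangularis R	R.PTRI	Frontal	F
27	Pericalcarine L	L.PCAL	Occipital	O
28	Pericalcarine R	R.PCAL	Occipital	O
29	Postcentral L	L.PoCG	Central	C
30	Postcentral R	R.PoCG	Central	C
31	Precentral L	L.PreCG	Central	C
32	Precentral R	R.PreCG	Central	C
33	Precuneus L	L.PCUN	Parietal	P
34	Precuneus R	R.PCUN	Parietal	P
35	Rostral middle frontal L	L.RMF	Frontal	F
36	Rostral middle frontal R	R.RMF	Frontal	F
37	Superior frontal L	L.SFG	Frontal	F
38	Superior frontal R	R.SFG	Frontal	F
39	Superior parietal L	L.SPG	Parietal	P
40	Superior parietal R	R.SPG	Parietal	P
41	Superior temporal L	L.STG	Temporal	T
42	Superior temporal R	R.STG	Temporal	T
43	Supramarginal L	L.SMG	Parietal	P
44	Supramarginal R	R.SMG	Parietal	P
45	Transverse temporal L	L.TRT	Temporal	T
46	Transverse temporal R	R.TRT	Temporal	T
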