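# reference discriminative pattern for the EC/EO contrast (28 regions, |Z| > 1.96)
# columns: index, region name, hemisphere, MNI x/y/z (mm), functional module, signed-rank Z
# note flags rows reproduced verbatim despite apparent typographical coordinate duplication
index	name	hem	x	y	z	module	z_value	note
1	parietal	R	18	-27	62	sensorimotor	3.34
2	frontal	R	53	-3	32	sensorimotor	2.92
3	precentral gyrus	L	-54	-9	23	sensorimotor	2.92
4	parietal	L	-47	-12	36	sensorimotor	2.92
5	parietal	L	-55	-22	38	sensorimotor	2.92
6	post insula	R	42	-24	17	sensorimotor	2.92
7	parietal	L	-24	-30	64	sensorimotor	2.92
8	IPS	L	-36	-69	40	default	2.50
9	basal ganglia	R	11	-24	2	cingulo-opercular	2.50
10	mid insula	L	-36	-12	15	sensorimotor	2.50
11	parietal	L	-47	-18	50	sensorimotor	2.50
12	post parietal	L	-41	-31	48	sensorimotor	2.50
13	sup parietal	R	34	-39	65	sensorimotor	2.50
14	mid insula	R	37	-2	-3	cingulo-opercular	2.09
15	vFC	L	-55	7	23	sensorimotor	2.09
16	precentral gyrus	R	58	-3	17	sensorimotor	2.09
17	mid insula	L	-42	-3	11	sensorimotor	2.09
18	mid insula	R	33	-12	16	sensorimotor	2.09
19	temporal	R	59	-13	8	sensorimotor	2.09
20	parietal	R	41	-23	55	sensorimotor	2.09
21	temporal	L	-53	-37	13	sensorimotor	2.09
22	occipital	L	-42	-76	26	default	-2.09
23	aPFC	L	-29	57	10	fronto-parietal	-2.09
24	dlPFC	L	-44	27	33	fronto-parietal	-2.09
25	post occipital	R	29	-81	14	occipital	-2.09
26	inf cerebellum	L	-21	-79	-33	cerebellum	-2.09
27	vmPFC	R	-36	-12	15	sensorimotor	-2.50	coordinate-duplicate
28	inf cerebellum	L	-47	-18	50	sensorimotor	-2.50	coordinate-duplicate
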