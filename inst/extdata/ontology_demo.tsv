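id	acronym	name	parent_id	r	g	b	volume_mm3	oversaturated
1	ROOT	whole brain	 	0	0	0	12.4	0
2	HPF	hippocampal formation	1	10	60	120	3.1	0
3	CTX	cortical plate	1	20	120	40	6.2	0
4	TH	thalamus	1	30	30	200	3.1	0
5	CA	Ammon's horn	2	120	200	255	1.2	0
6	DG	dentate gyrus	2	100	180	235	0.7	0
7	SUB	subiculum	2	90	160	215	1.2	0
8	MO	somatomotor areas	3	255	120	80	2.6	0
9	SS	somatosensory areas	3	235	100	60	2.4	0
10	VIS	visual areas	3	215	80	40	1.2	0
11	GENv	geniculate group	4	60	255	120	1.6	0
12	RT	reticular nucleus	4	40	235	100	1.5	1
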