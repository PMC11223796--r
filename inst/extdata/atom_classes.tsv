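class_id	name	descr	eps	rmin2	gref	lambda	vol
1	CC	carbonyl/amide/guanidinium carbon	0.11	2	0	3.5	14.7
2	CT1	aliphatic CH	0.032	2	-0.19	3.5	23.7
3	CT2	aliphatic CH2	0.056	2.01	0.37	3.5	22.4
4	CT3	aliphatic CH3	0.078	2.04	1.41	3.5	30
5	CAR	aromatic carbon	0.07	1.99	0.057	3.5	18.4
6	NAM	amide/ring nitrogen	0.2	1.85	-5.45	3.5	4.4
7	NPOS	charged nitrogen	0.2	1.85	-20	6	11.2
8	OCA	carbonyl oxygen	0.12	1.7	-5.33	3.5	10.8
9	OHX	hydroxyl oxygen	0.152	1.77	-6.7	3.5	10.8
10	ONEG	carboxylate oxygen	0.12	1.7	-10	6	10.8
11	S	sulfur	0.45	2	-3.24	3.5	14.7
12	NPRO	proline nitrogen	0.2	1.85	-1	3.5	4.4
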