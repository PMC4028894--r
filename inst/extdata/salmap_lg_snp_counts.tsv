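linkage_group	chromosome	snps_crimap	ordered_br5_mother	ordered_br6_mother	ordered_br5_father	ordered_br6_father
1	2	244	59	23	73	68
2	10	350	102	86	88	79
3	14	197	31	35	68	76
4	6	283	47	43	84	79
5	13	306	67	84	84	85
6	12	257	72	46	81	71
7	24	138	27	47	51	39
8	15	520	78	47	69	84
9	11	226	50	64	67	49
10	9	394	95	94	113	103
11	3	336	48	92	98	103
12	5	224	24	29	74	68
13	19	197	49	58	43	59
14	21	152	38	40	47	33
15	27	132	31	39	40	43
16	18	209	33	58	65	67
17	1	442	70	78	130	129
18	23	155	36	33	55	51
19	8	42	8	0	13	15
20	25	115	20	33	26	23
21	26	113	25	25	30	35
22	17	158	19	44	33	64
23	16	215	58	49	66	55
24	7	169	22	17	57	56
25	20	237	65	77	62	73
28	4	220	19	32	80	83
30	29	116	43	23	36	37
31	28	132	34	37	42	39
32	22	179	41	66	58	51
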