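groups	chromosomes	shared_contigs	ancestral
4/11	6/3	25	E
10/25	9/20	11	G/H
1/12	2/5	9	B
9/21	11/26	9	J
3/11	14/3	8	M
22/24	17/7	8	K
1/6	2/12	5	D
3/15	14/27	4	B
2/23	10/16	3	M,J/K
2/18	10/23	3	M
7/25	24/20	3	I
19/28	8/4	3	-
5/17	13/1	2	I
9/28	11/4	2	G/H
3/14	14/21	1	-
5/28	13/4	1	G/H
6/32	12/22	1	L
16/17	18/1	1	D
17/31	1/28	1	D
22/23	17/16	1	K
22/30	17/29	1	K
17/32	1/22	1	-
12/17	5/18	1	-
10/32	9/22	1	-
9/25	11/20	1	G/H,I
4/6	6/12	1	-
2/25	10/20	1	-
2/6	10/12	1	-
9/14	11/21	1	-
3/13/17	14/19/1	1	3&13=M
1/6/32	2/12/22	1	1&6=D
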