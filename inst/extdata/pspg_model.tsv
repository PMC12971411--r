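position	residues	weight
1	W	2
2	AS	1
3	P	2
4	Q	2
5	VIL	1
6	E	2
7	VIL	1
8	LIV	1
9	AGS	1
10	H	1
11	PAS	1
12	AVG	1
13	VIL	1
14	G	1
15	CGS	1
16	FW	1
17	VIL	1
18	TS	1
19	H	2
20	C	2
21	G	2
22	W	2
23	N	2
24	S	2
25	TS	1
26	LIV	1
27	E	2
28	S	1
29	IVL	1
30	S	1
31	AGC	1
32	G	1
33	VIL	1
34	P	1
35	MLV	1
36	VIA	1
37	A	1
38	W	2
39	P	2
40	FL	1
41	FLA	1
42	A	1
43	DE	1
44	Q	2
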