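id	start	end	repeat_type
1	0	48	-
2	48	93	type1
3	93	144	type1
4	144	192	type1
5	192	237	type1
6	237	291	type2
7	291	339	type2
8	339	375	-
9	375	426	type2
10	426	486	-
11	486	534	type3
12	534	579	type3
13	579	630	type3
14	630	678	-
15	678	735	type4
16	735	780	type4
17	780	816	-
18	816	867	type4
19	867	915	type4
20	915	969	type5
21	969	1014	type5
22	1014	1062	type5
23	1062	1113	type5
24	1113	1158	type5
25	1158	1206	type6
26	1206	1260	type6
27	1260	1470	-
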