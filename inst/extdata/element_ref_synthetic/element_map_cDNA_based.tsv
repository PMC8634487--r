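id	start	end	repeat_type
1	0	48	-
2	48	69	-
3	69	93	-
4	93	144	-
5	144	168	-
6	168	192	-
7	192	237	-
8	237	264	-
9	264	291	-
10	291	339	-
11	339	357	-
12	357	375	-
13	375	399	-
14	399	426	-
15	426	486	-
16	486	579	-
17	579	678	-
18	678	780	-
19	780	867	-
20	867	969	-
21	969	1062	-
22	1062	1113	-
23	1113	1158	-
24	1158	1206	-
25	1206	1260	-
26	1260	1470	-
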