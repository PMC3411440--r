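k	promethee2_value	promethee2_order	topsis_value	topsis_order	wsm_value	wsm_order
2	-0.2265	8	0.400601	9	-0.25409	9
3	0.1125	3	0.537494	5	-0.1994	3
4	-0.17975	7	0.451931	8	-0.2342	7
5	0.102	4	0.539354	4	-0.2154	4
6	-0.31675	9	0.481188	7	-0.2463	8
7	0.02575	5	0.544836	3	-0.2213	5
8	-0.10825	6	0.529223	6	-0.2336	6
9	0.29475	2	0.626924	1	-0.1827	1
10	0.29625	1	0.603641	2	-0.185	2
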