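#id	kind	breakpoint	time
1	sample		0
2	sample		0
3	sample		0
4	recombination	2	1
5	common_ancestor		2
6	recombination	3	3
7	recombination	5	4
8	common_ancestor		5
9	recombination	3	6
10	common_ancestor		7
11	common_ancestor		8
12	recombination	4	9
13	recombination	6	10
14	recombination	6	11
15	common_ancestor		12
16	common_ancestor		13
17	common_ancestor		14
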