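#child	parent	intervals
1	8	0,7
2	5	0,7
3	4	0,7
4	5	2,7
4	7	0,2
5	6	0,7
6	10	3,7
6	11	0,3
7	8	0,2
8	9	0,7
9	11	0,3
9	12	3,7
10	13	3,7
12	14	4,7
12	16	3,4
13	15	3,6
13	16	6,7
14	15	6,7
14	16	4,6
15	16	3,7
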