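#child	parent	intervals
1	5	0,2
1	6	2,10
2	7	0,10
3	5	7,10
3	6	0,7
4	8	0,10
5	9	0,10
6	11	0,10
7	9	0,10
8	11	0,10
9	14	0,10
10	15	0,10
11	14	0,10
12	16	0,10
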