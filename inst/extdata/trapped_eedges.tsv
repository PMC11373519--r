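#child	parent	side
1	8	-
2	5	-
3	4	-
4	5	R
4	7	L
5	6	-
6	10	R
6	11	L
7	8	L
7	10	R
8	9	-
9	11	L
9	12	R
10	13	-
11	17	-
12	14	R
12	16	L
13	15	L
13	16	R
14	15	R
14	16	L
15	16	-
16	17	-
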