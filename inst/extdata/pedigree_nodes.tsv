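#id	time	is_sample	metadata
1	0	1	A d1
2	0	1	B d1
3	0	1	C d2
4	0	1	D d2
5	1	0	E d3
6	1	0	F d3
7	1	0	G d4
8	1	0	H d4
9	2	0	I d5
10	2	0	J d5
11	2	0	K d6
12	2	0	L d6
13	3	0	M d7
14	3	0	N d7
15	3	0	O d8
16	3	0	P d8
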