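#id	time	is_sample	metadata
1	0	1	
2	0	1	
3	0	1	
4	1	0	
5	2	0	
6	3	0	
7	4	0	
8	5	0	
9	6	0	
10	7	0	
11	8	0	
12	9	0	
13	10	0	
14	11	0	
15	12	0	
16	13	0	
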