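component	component_size	class	class_size	teacher_found	missing_nodes
1	26	1B	25	1	0
2	22	5A	22	1	1
3	23	3B	22	1	0
4	25	5B	24	1	0
5	27	2B	26	1	0
6	23	2A	22	1	0
7	24	3A	23	1	0
8	22	4A	21	1	0
9	24	1A	23	1	0
11	24	4B	23	1	0
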