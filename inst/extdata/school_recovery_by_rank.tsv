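n_components	core_consistency	matched_classes	class_nodes	covered_nodes	recall
2	99.966	1	25	25	1
3	99.885	1	25	25	1
4	97.363	1	25	25	1
5	96.984	2	46	46	1
6	98.134	4	94	91	0.99386
7	96.604	4	94	91	0.99386
8	95.451	7	163	162	0.99386
9	95.408	8	185	184	0.99459
10	94.815	9	208	207	0.99519
11	92.639	9	208	207	0.99519
12	92.526	10	231	230	0.99567
13	93.472	10	231	230	0.99567
14	78.326	10	231	230	0.99567
15	76.683	10	231	230	0.99567
16	73.5	10	231	230	0.99567
17	65.185	10	231	230	0.99567
18	60.981	10	231	230	0.99567
19	56.218	10	231	230	0.99567
20	51.709	10	231	230	0.99567
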