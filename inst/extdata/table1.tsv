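signal	window_low	window_high	max_percent	candidates
4878	3878	5878	21	146
5456	4456	6456	18	124
5667	4667	6667	18	134
6199	5199	7199	16	138
6452	5452	7452	15	150
11353	10353	12353	9	465
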