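signal	candidates	noise_n	noise_pct	ouabain_n	ouabain_pct	either_n	either_pct	reduction_pct
4878	146	6	4	16	11	21	14	86
5456	124	4	3	19	15	22	18	82
5667	134	4	3	21	16	24	18	82
6199	138	6	4	22	16	25	18	82
6452	150	8	5	28	19	32	21	79
11353	465	37	8	117	25	128	28	72
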