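signals	accession	protein	chain_start	chain_end	chain_mass_da	probe_set	p_value
4878 5456 5667	P01027	Complement C3g fragment	955	1001	4950	NA	NA
4878	P19221	Prothrombin (Thrombin Light Chain)	325	360	4047	1418897_at	0.045
11353	P01027	C3-beta-c	569	666	10470	NA	NA
11353	P62806	Histone H4	2	103	11236	NA	NA
11353	P32848	Parvalbumin alpha	2	110	11799	1417653_at	0.024
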