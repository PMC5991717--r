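lake	species	post_mean	ci_low	ci_high
Lake of the Woods	Walleye	4.24	3.12	5.34
Lake Vermilion	Walleye	2.35	0.68	4.01
Lake Kabetogama	Walleye	-0.13	-1.32	0.97
Namakan Lake	Walleye	0.88	-0.37	2.11
Rainy Lake	Walleye	2.09	1.3	2.87
Sand Point Lake	Walleye	0.58	-1.08	2.31
Lake of the Woods	Northern Pike	0.94	0.76	1.11
Lake Vermilion	Northern Pike	-0.36	-0.6	-0.13
Lake Kabetogama	Northern Pike	0.66	0.26	1.06
Namakan Lake	Northern Pike	0.86	0.46	1.27
Rainy Lake	Northern Pike	0.48	0.17	0.81
Sand Point Lake	Northern Pike	0.94	0.45	1.44
Lake of the Woods	Yellow Perch	-0.51	-1.63	0.62
Lake Vermilion	Yellow Perch	-5.85	-9.5	-2.26
Lake Kabetogama	Yellow Perch	4.23	2.93	5.57
Namakan Lake	Yellow Perch	-0.1	-0.77	0.58
Rainy Lake	Yellow Perch	0.68	-0.13	1.62
Sand Point Lake	Yellow Perch	-0.86	-1.52	-0.27
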