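id	phase	t00	t01	t02	t03
gene_a	G1	0.52	-0.31	0.87	-0.14
gene_b	S	-0.23	0.44	-0.65	0.91
gene_c		1.02	0.33	-0.48	0.27
gene_d	G2	-0.77	0.58	0.12	-0.36
gene_e	M	0.15	-0.92	0.41	0.68
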