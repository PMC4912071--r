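gene_id	value_a	value_b	log2_fc	p_value	q_value	significant	protein_names	gene_names	go_terms
GK5S-1542	5.2	1512.1	8.2	0.001	0.001	yes	Citrate synthase 3 (EC 2.3.3.16)	CIT3	GO:0019543
GK5S-1543	27.5	901.5	5.0	0.001	0.001	yes	Probable 2-methylcitrate dehydratase (EC 4.2.1.79)	PDH1	GO:0019543
GK5S-2306	15.5	436.9	4.8	0.001	0.001	yes	Mitochondrial 2-methylisocitrate lyase (EC 4.1.3.30)	ICL2	GO:0019543
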