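snp_id	chrom	pos	cytoband	gene_label	allele1	allele2	stage	n_case	n_control	freq_case	freq_control	or	ci_low	ci_high	p
rs340630	4	88177419	4q21	AFF1	A	G	gwas	891	3383	0.56	0.51	1.22	1.10	1.36	1.5e-4
rs340630	4	88177419	4q21	AFF1	A	G	rep1	550	646	0.57	0.49	1.40	1.19	1.64	4.6e-5
rs340630	4	88177419	4q21	AFF1	A	G	rep2	820	27911	0.56	0.53	1.14	1.03	1.26	0.0094
rs340630	4	88177419	4q21	AFF1	A	G	combined	2261	31940	0.56	0.52	1.21	1.14	1.30	8.3e-9
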