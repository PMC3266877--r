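snp_id	chrom	pos	cytoband	gene_label	allele1	allele2	n_case	n_control	freq_case	freq_control	or	ci_low	ci_high	p
rs10168266	2	191644049	2q32	STAT4	T	C	891	3384	0.37	0.27	1.59	1.42	1.78	2.7e-16
rs9501626	6	32508322	6p21	HLA	A	C	891	3381	0.20	0.12	1.86	1.62	2.13	1.0e-18
rs2230926	6	138237759	6q23	TNFAIP3	G	T	891	3377	0.11	0.069	1.75	1.47	2.08	1.9e-10
rs6964720	7	75018280	7q11	HIP1	G	A	891	3384	0.25	0.19	1.43	1.27	1.63	1.3e-8
rs2254546	8	11381089	8p23	BLK	G	A	891	3384	0.78	0.72	1.42	1.25	1.61	4.1e-8
rs6590330	11	127816269	11q24	ETS1	A	G	891	3368	0.48	0.39	1.44	1.30	1.60	1.3e-11
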