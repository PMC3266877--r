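snp_id	chrom	pos	cytoband	gene_label	allele1	allele2	freq_case	freq_control	or	ci_low	ci_high	p	eqtl_positive	discovered_caucasian	discovered_asian
rs2205960	1	171458098	1q25	TNFSF4	T	G	0.23	0.18	1.35	1.19	1.54	3.0e-6	FALSE	TRUE	FALSE
rs3024505	1	205006527	1q32	IL10	A	G	0.019	0.014	1.34	0.90	2.00	0.15	FALSE	TRUE	FALSE
rs13385731	2	33555394	2p22	RASGRP3	C	T	0.90	0.87	1.37	1.15	1.64	6.0e-4	TRUE	FALSE	TRUE
rs10168266	2	191644049	2q32	STAT4	T	C	0.37	0.27	1.59	1.42	1.78	2.7e-16	FALSE	TRUE	FALSE
rs6445975	3	58345217	3p14	PXK	G	T	0.25	0.23	1.09	0.96	1.23	0.18	TRUE	TRUE	FALSE
rs10516487	4	102970099	4q24	BANK1	G	A	0.91	0.89	1.28	1.07	1.53	0.0070	FALSE	TRUE	FALSE
rs10036748	5	150438339	5q33	TNIP1	T	C	0.75	0.72	1.16	1.03	1.31	0.014	FALSE	FALSE	TRUE
rs9501626	6	32508322	6p21	HLA-DRB1	A	C	0.20	0.12	1.86	1.62	2.13	1.0e-18	FALSE	TRUE	FALSE
rs548234	6	106674727	6q21	PRDM1	C	T	0.40	0.34	1.30	1.16	1.44	2.3e-6	TRUE	TRUE	FALSE
rs2230926	6	138237759	6q23	TNFAIP3	G	T	0.11	0.069	1.75	1.47	2.08	1.9e-10	TRUE	TRUE	FALSE
rs849142	7	28152416	7p15	JAZF1	C	T	0.999	0.999	2.72	0.25	29.8	0.41	FALSE	TRUE	FALSE
rs4917014	7	50276409	7p12	IKZF1	T	G	0.58	0.53	1.24	1.11	1.38	8.1e-5	FALSE	FALSE	TRUE
rs6964720	7	75018280	7q11	HIP1	G	A	0.25	0.19	1.43	1.27	1.62	1.3e-8	FALSE	FALSE	TRUE
rs4728142	7	128361203	7q32	IRF5	A	G	0.16	0.11	1.48	1.28	1.72	2.4e-7	TRUE	TRUE	FALSE
rs2254546	8	11381089	8p23	BLK	G	A	0.78	0.72	1.42	1.25	1.61	4.1e-8	TRUE	TRUE	FALSE
rs1913517	10	49789060	10q11	WDFY4	A	G	0.32	0.28	1.20	1.07	1.35	0.0013	FALSE	FALSE	TRUE
rs4963128	11	579564	11p15	KIAA1542	T	C	0.98	0.97	1.58	1.03	2.44	0.038	TRUE	TRUE	FALSE
rs2732552	11	35041168	11p13	PDHX,CD44	T	C	0.75	0.73	1.13	1.00	1.27	0.056	FALSE	TRUE	FALSE
rs4639966	11	118078729	11q23	intergenic	T	C	0.32	0.28	1.22	1.09	1.36	7.3e-4	FALSE	FALSE	TRUE
rs6590330	11	127816269	11q24	ETS1	A	G	0.48	0.39	1.44	1.30	1.60	1.3e-11	FALSE	FALSE	TRUE
rs1385374	12	127866647	12q24	SLC15A4	T	C	0.19	0.16	1.21	1.06	1.38	0.0057	FALSE	FALSE	TRUE
rs7329174	13	40456110	13q14	ELF1	G	A	0.30	0.25	1.32	1.18	1.49	2.2e-6	FALSE	FALSE	TRUE
rs7197475	16	30550368	16p11	intergenic	T	C	0.12	0.10	1.20	1.02	1.41	0.031	FALSE	FALSE	TRUE
rs11150610	16	31241737	16p11	ITGAM	C	A	0.20	0.19	1.07	0.94	1.22	0.32	TRUE	TRUE	FALSE
rs12949531	17	13674531	17p12	intergenic	T	C	0.28	0.27	1.02	0.91	1.15	0.73	FALSE	TRUE	FALSE
rs463426	22	20139185	22q11	HIC2,UBE2L3	T	C	0.52	0.48	1.20	1.08	1.33	6.1e-4	FALSE	TRUE	FALSE
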