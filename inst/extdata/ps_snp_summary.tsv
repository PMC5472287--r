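snp_id	chrom_band	gene	risk_allele	other_allele	raf_ctrl	raf_case	or	ci_lo	ci_hi	p
rs7552167	1p36.11	IL28RA	G	A	0.833	0.871	1.36	1.05	1.75	0.017
rs7530511	1p31.3	IL23R	C	T	0.851	0.866	1.13	0.87	1.46	0.37
rs11209026	1p31.3	IL23R	G	A	0.960	0.979	1.98	1.14	3.44	0.013
rs2476601	1p13.2	PTPN22	G	A	0.859	0.869	1.10	0.85	1.44	0.46
rs4112788	1q21.3	LCE3C-LCE3B	C	T	0.627	0.667	1.19	0.99	1.44	0.07
rs6701216	1q21.3	LCE1C	T	C	0.147	0.168	1.18	0.92	1.51	0.20
rs702873	2p13-p12	REL	G	A	0.557	0.642	1.42	1.18	1.71	2.5e-4
rs10865331	2p15	B3GNT2	A	G	0.400	0.467	1.32	1.10	1.60	2.5e-3
rs17716942	2q24	IFIH1	T	C	0.893	0.898	1.07	0.79	1.43	0.68
rs30187	5q15	ERAP1	T	C	0.313	0.344	1.15	0.95	1.40	0.14
rs20541	5q31.1	IL13	C	T	0.739	0.782	1.27	1.02	1.56	0.026
rs1024995	5q33.1	TNIP1	C	T	0.137	0.166	1.26	0.98	1.62	0.07
rs3212227	5q33.3	IL12B	A	G	0.774	0.853	1.69	1.34	2.14	1.2e-5
rs6887695	5q33.3	IL12B	G	A	0.697	0.760	1.38	1.12	1.69	2.1e-3
rs2431697	5q33.3	PTTG1	C	T	0.396	0.430	1.15	0.96	1.38	0.13
rs6908425	6p22.3	CDKAL1	C	T	0.775	0.811	1.24	0.99	1.55	0.051
rs1150735	6p21.3	RNF39	T	C	0.344	0.367	1.10	0.91	1.33	0.31
rs1264569	6p21.3	TRIM39/RPP21	A	G	0.794	0.871	1.75	1.37	2.24	1.1e-5
rs879882	6p21.31	POU5F1	C	T	0.615	0.723	1.63	1.35	1.98	3.4e-7
rs4406273	6p21.33	HLA-C	A	G	0.112	0.335	3.98	3.13	5.06	4.6e-33
rs10484554	6p21.33	HLA-C	T	C	0.222	0.444	2.80	2.29	3.41	5e-26
rs13437088	6p21.33	MICA	T	C	0.303	0.404	1.57	1.30	1.90	3.3e-6
rs240993	6q21	TRAF3IP2	T	C	0.296	0.319	1.11	0.92	1.35	0.28
rs610604	6p23.3	TNFAIP3	C	T	0.305	0.325	1.09	0.90	1.33	0.37
rs7007032	8p23.2	CSMD1	T	C	0.690	0.691	1.00	0.82	1.22	0.99
rs12580100	12q13	RPS26	A	G	0.839	0.856	1.14	0.89	1.46	0.31
rs3751385	13q11-q12	GJB2	C	T	0.833	0.843	1.07	0.84	1.37	0.57
rs7993214	13q13.3	COG6	C	T	0.622	0.628	1.03	0.85	1.24	0.79
rs8016947	14q13	NFKBIA	G	A	0.531	0.591	1.27	1.06	1.53	7.5e-3
rs4780355	16p13.13	SOCS1	T	C	0.668	0.680	1.06	0.87	1.28	0.58
rs12445568	16p11.2	FBXL19	C	T	0.406	0.427	1.09	0.91	1.31	0.35
rs4795067	17q11.2	NOS2	G	A	0.347	0.392	1.21	1.01	1.46	0.049
rs744166	17q21.31	STAT3	C	T	0.370	0.371	1.00	0.83	1.21	0.97
rs12720356	19p13.2	TYK2	T	C	0.929	0.951	1.49	1.01	2.18	0.042
rs892085	19p13.2	IL3/CARM1	T	C	0.602	0.634	1.15	0.95	1.38	0.15
rs9304742	19q13.41	ZNF816	C	T	0.320	0.339	1.09	0.90	1.32	0.36
rs1008953	20q12	SDC4	G	A	0.745	0.798	1.35	1.09	1.68	5.9e-3
rs2235617	20q13.13	RNF114	G	A	0.522	0.568	1.20	1.00	1.44	0.045
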