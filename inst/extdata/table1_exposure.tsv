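snp	chr	effect_allele	other_allele	eaf	beta	se	pval	n	trait
rs4806073	19	C	T	0.07	0.280	0.013	8.08e-106	315268	albumin
rs1260326	2	T	C	0.61	0.153	0.007	5.02e-120	315268	albumin
rs11078597	17	C	T	0.19	0.170	0.008	3.34e-94	315268	albumin
rs13381710	18	G	A	0.30	0.066	0.007	6.28e-21	315268	albumin
rs16948098	15	A	G	0.04	0.215	0.016	2.02e-39	315268	albumin
rs739347	19	T	C	0.90	0.188	0.011	5.43e-69	315268	albumin
rs3751991	17	A	C	0.10	0.427	0.017	1.18e-142	315268	total_protein
rs204999	6	A	G	0.69	0.250	0.011	1.18e-114	315268	total_protein
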