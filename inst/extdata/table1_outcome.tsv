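snp	chr	effect_allele	other_allele	eaf	beta	se	pval	n	trait
rs4806073	19	C	T	NA	-0.006	0.034	0.873	356432	albumin
rs1260326	2	T	C	NA	0.040	0.018	0.023	356432	albumin
rs11078597	17	C	T	NA	-0.007	0.022	0.757	356432	albumin
rs13381710	18	G	A	NA	-0.020	0.019	0.295	356432	albumin
rs16948098	15	A	G	NA	-0.082	0.043	0.060	356432	albumin
rs739347	19	T	C	NA	-0.042	0.029	0.141	356432	albumin
rs3751991	17	A	C	NA	-0.038	0.029	0.182	356432	total_protein
rs204999	6	A	G	NA	-0.058	0.019	0.002	356432	total_protein
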