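panel	direction	chrom	start	end	gene	snp_id
neuronal	more_accessible_in_LOAD	chr6	32551592	32552707	HLA-DRB1	rs9271058
neuronal	more_accessible_in_LOAD	chr6	32489394	32490069	HLA-DRB1	rs9271058
neuronal	less_accessible_in_LOAD	chr20	54994099	54994641	CASS4	rs6024870
neuronal	less_accessible_in_LOAD	chr8	27209401	27210247	PTK2B	rs73223431
neuronal	less_accessible_in_LOAD	chr8	27563212	27563671	CLU	rs9331896
female_glia	more_accessible_in_LOAD	chr10	11784165	11784736	ECHDC3	rs7920721
female_glia	less_accessible_in_LOAD	chr14	92966426	92967442	SLC24A4	rs12881735
female_glia	less_accessible_in_LOAD	chr16	19894588	19895301	IQCK	rs7185636
female_glia	less_accessible_in_LOAD	chr17	61627113	61628372	ACE	rs138190086
female_glia	less_accessible_in_LOAD	chr19	1101756	1102160	ABCA7	rs3752246
female_glia	less_accessible_in_LOAD	chr19	45416036	45416558	APOE	rs429358
female_glia	less_accessible_in_LOAD	chr19	45428555	45429362	APOE	rs429358
female_glia	less_accessible_in_LOAD	chr19	45454352	45455071	APOE	rs429358
female_glia	less_accessible_in_LOAD	chr7	100025783	100028055	NYAP1	rs12539172
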