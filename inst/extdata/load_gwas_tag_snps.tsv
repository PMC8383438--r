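snp_id	chrom	pos	label	printed_window_start	printed_window_end
rs9271058	chr6	32575406	HLA-DRB1	32475406	32675406
rs6024870	chr20	54997568	CASS4	54897568	55097568
rs73223431	chr8	27219987	PTK2B	27119987	27319987
rs9331896	chr8	27467686	CLU	27367686	27567686
rs7920721	chr10	11720308	ECHDC3	11620308	11820308
rs12881735	chr14	92932828	SLC24A4	92832828	93032828
rs7185636	chr16	19808163	IQCK	19708163	19908163
rs138190086	chr17	61538148	ACE	61438148	61638148
rs3752246	chr19	1056492	ABCA7	956492	1156492
rs429358	chr19	45411941	APOE	45311941	45511941
rs12539172	chr7	100091795	NYAP1	99991795	100191795
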