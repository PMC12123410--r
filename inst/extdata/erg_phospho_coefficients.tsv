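protein	site	coefficient	kinase
MYH9	S1943	1.209	CSNK2A1
MYH11	S1954	1.100	NA
ALB	S82	0.881	NA
NEXN	S16	0.637	NA
PRKCE	T710	0.503	MTOR
MYH11	S23	0.282	NA
FGA	S609	0.203	CSNK2A1
ALB	T551	0.122	NA
SSR3	S105	0.100	NA
PRKCD	S683	0.091	NA
FHOD1	S549	0.044	NA
CTNND1	S847	-1.208	NA
IQGAP1	S330	-1.380	NA
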