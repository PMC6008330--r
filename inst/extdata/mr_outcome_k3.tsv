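SNP	CHR	POS	EA	OA	BETA	SE	P	N	EAF
rs1	6	32551000	A	G	-0.20	0.05	6.3e-05	156	0.36
rs2	6	32552000	A	G	-0.34	0.06	1.5e-08	156	0.41
rs3	6	32553000	A	G	-0.52	0.07	1.1e-13	156	0.28
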