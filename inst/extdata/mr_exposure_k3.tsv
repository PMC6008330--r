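SNP	CHR	POS	EA	OA	BETA	SE	P	N	EAF
rs1	6	32551000	A	G	0.12	0.02	2.0e-09	279	0.35
rs2	6	32552000	A	G	0.20	0.025	1.4e-15	279	0.42
rs3	6	32553000	A	G	0.31	0.03	6.1e-25	279	0.27
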