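id	rs1	rs2	rs3
rs1	1	0.5	0.2
rs2	0.5	1	0.4
rs3	0.2	0.4	1
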