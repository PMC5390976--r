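reaction_id	equation	reversible
R1	 = A	0
R2	A = 	1
R3	A = 	0
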