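genotype	breeding_type	total	no_tail	short_tail	kinked_tail	long_tail	runt_deaths
dexon6/dexon6	intercross	0	0	0	0	0	0
dexon6/+	intercross	63	4	9	8	42	0
+/+	intercross	35	0	0	0	35	0
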