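genotype	breeding_type	total	no_tail	short_tail	kinked_tail	long_tail	runt_deaths
dexon6/insRCS2	het_x_het	7	7	0	0	0	2
dexon6/+	het_x_het	11	0	0	1	10	0
insRCS2_or_wt/+	het_x_het	12	0	0	0	12	0
dexon6/insRCS2	het_x_hom	12	12	0	0	0	4
insRCS2/+	het_x_hom	30	0	0	0	30	0
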