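reaction_id	name	equation	lb	ub	gene_rule
MVAS	acetyl-CoA to mevalonate (lumped)	3 accoa_c -> mev_c	0	1000	mvaS_t
DPMVD	mevalonate decarboxylase (MVA terminal)	mev_c -> ipp_c + co2_c	0	1000	mvaD_t
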