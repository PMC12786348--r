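reaction_id	name	equation	lb	ub	gene_rule
CDS	chrysanthemyl diphosphate synthase	2 dmapp_c -> cdpchr_c	0	1000	cds_t
NUDX1	CDP-chrysanthemol phosphatase	cdpchr_c -> chol_c	0	1000	nudix1_t
NUDX2	DMAPP phosphatase shunt	dmapp_c -> dmap_c	0	1000	nudix2_t
ADH2	chrysanthemol dehydrogenase	chol_c -> chal_c	0	1000	adh2_t
ALDH1	chrysanthemal dehydrogenase	chal_c -> chac_c	0	1000	aldh1_t
EX_CS_OH	chrysanthemol exchange	chol_c ->	0	1000	NA
EX_chac	chrysanthemic acid exchange	chac_c ->	0	1000	NA
EX_dmap	DMAP exchange	dmap_c ->	0	1000	NA
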