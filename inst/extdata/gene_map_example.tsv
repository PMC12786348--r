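template_id	target_id	match_score
b0421	ispA_t	1e-120
b3060	idi_t	3e-85
b2889	gpph_t	2e-40
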