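# Gene-to-family map for paralogous flanking markers.
gene_id	family_id
SNX32	SNX
SNX5	SNX
BANF1	BANF
BANF2	BANF
AKT2	AKT2
AKT2a	AKT2
AKT2b	AKT2
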