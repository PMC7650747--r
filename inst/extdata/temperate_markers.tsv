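accession	name	role
PF00589	Phage_integrase	tyrosine integrase
PF02899	Phage_int_SAM_1	tyrosine integrase N-terminal domain
PF13495	Phage_int_SAM_4	tyrosine integrase N-terminal domain
PF00239	Resolvase	serine recombinase catalytic domain
PF07508	Recombinase	serine recombinase large-terminal domain
PF01381	HTH_3	immunity-repressor-type helix-turn-helix
PF12844	HTH_19	immunity-repressor-type helix-turn-helix
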