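protein_1	protein_2	kd_pp_uM	source
AP-2	EPN1	NA	user-supplied: per-pair protein-protein affinities are not shipped; fill in from primary literature
AP-2	SNAP91/AP180	NA	user-supplied
AP-2	FCHO1	NA	user-supplied
AP-2	DAB2	NA	user-supplied
SH3GL2/Endophilin	SH3GL2/Endophilin	NA	user-supplied (homodimer)
FCHO1	FCHO2	NA	user-supplied
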