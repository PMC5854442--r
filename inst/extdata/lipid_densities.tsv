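lipid	context	density_per_um2	provenance
PI(4,5)P2	plasma_membrane	25000	mouse fibroblast average, ~1 percent of plasma-membrane lipid
PI(4,5)P2	clathrin_invitro	54668	extracted from in vitro clathrin polymerization assay conditions
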