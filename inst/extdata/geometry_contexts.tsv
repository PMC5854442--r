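context	V_um3	A_um2	v_over_a_um	provenance
human_cell	1200	767	1.5645	cytoplasmic volume and plasma-membrane area, human cell
yeast_cell	37.2	75.8	0.4908	cytoplasmic volume and plasma-membrane area, yeast cell
kinetics_reference	50	65.63	0.7618	reference system for ODE/RD timescale comparisons
clathrin_invitro	NA	NA	9.46	ratio extracted from in vitro clathrin polymerization assay conditions
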