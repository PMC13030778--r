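# Published caliper distances (Angstrom) for insect Dicer-2 orthologs:
# 3' pocket <-> RNase III A and 5' pocket <-> RNase III B centroid distances,
# the reported per-species mean, and the reported siRNA length class (nt).
# Note: the reported T. castaneum mean (59.8) differs from the arithmetic mean
# of its two printed distances ((58.8+61.2)/2 = 60.0); see package vignette.
structure_id	species	d_3p_riiia	d_5p_riiib	reported_mean	reported_nt
dmel	D. melanogaster	61.0	59.6	60.3	21
tcas	T. castaneum	58.8	61.2	59.8	21
bter	B. terrestris	61.7	62.7	62.2	22
lmig	L. migratoria	63.7	60.9	62.3	22
tni	T. ni	53.6	63.1	58.3	20
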