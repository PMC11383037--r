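# Non-synonymous caspase variants in 8 inbred rat lines, transcribed from
# the published table. Class encodes the published shading: light shading
# (italics) = unlikely to disrupt function, dark = potential to disrupt.
# The caspase-12 exon-7 1 bp insertion (1bp_ins, CDS-relative) is present in
# all 8 strains; the published interpretation is that the reference rat
# assembly carries a frameshift error at this position and the strains
# restore the reading frame.
strain	gene	variant	class
ACI_N	casp1	Q343R	unlikely
ACI_N	casp11	V60A	unlikely
ACI_N	casp12	1bp_ins	unlikely
BN_SsN	casp12	1bp_ins	unlikely
BUF_N	casp1	Q343R	unlikely
BUF_N	casp11	V60A	unlikely
BUF_N	casp12	1bp_ins	unlikely
F344_N	casp1	Q343R	unlikely
F344_N	casp11	V60A	unlikely
F344_N	casp12	1bp_ins	unlikely
M520_N	casp1	Q343R	unlikely
M520_N	casp11	V60A	unlikely
M520_N	casp12	1bp_ins	unlikely
MR_N	casp1	Q343R	unlikely
MR_N	casp11	F115L	potential_impact
MR_N	casp12	1bp_ins	unlikely
WKY_N	casp1	Q343R	unlikely
WKY_N	casp11	F115L	potential_impact
WKY_N	casp12	1bp_ins	unlikely
WN_N	casp1	Q343R	unlikely
WN_N	casp12	1bp_ins	unlikely
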