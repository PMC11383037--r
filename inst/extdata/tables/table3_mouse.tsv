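# Non-synonymous caspase variants in 16 inbred mouse lines, transcribed from
# the published table of strain variants. One row per strain x variant; the
# class column encodes the published shading: light shading (italics) =
# unlikely to disrupt function (the alternate residue occurs in another
# rodent homolog), dark shading = potential to disrupt function (the variant
# alters a highly conserved site). Strains carrying no variants are listed
# with variant "none" so the full strain panel is recoverable.
# Column-to-gene grouping: the printed gene spans are typographically
# ambiguous; this transcription assigns E126K..C331Y to caspase-11 and
# A3V..N330T to caspase-12, the unique assignment consistent with the
# published avoid (8 strains) and clean (7 strains) lists.
strain	gene	variant	class
129S1_SvImJ	casp11	5bp_del	potential_impact
129S1_SvImJ	casp11	C331Y	potential_impact
129S1_SvImJ	casp12	E46D	potential_impact
129S1_SvImJ	casp12	M130I	potential_impact
129S1_SvImJ	casp12	L137I	potential_impact
cAST_EiJ	casp1	R33K	unlikely
cAST_EiJ	casp11	G257E	potential_impact
cAST_EiJ	casp12	P105L	potential_impact
cAST_EiJ	casp12	M130I	unlikely
cAST_EiJ	casp12	Q153K	potential_impact
cAST_EiJ	casp12	H270R	unlikely
cAST_EiJ	casp12	N311S	potential_impact
pWK_PhJ	casp1	R33K	unlikely
pWK_PhJ	casp11	C331Y	potential_impact
pWK_PhJ	casp12	L137I	unlikely
pWK_PhJ	casp12	Q153K	potential_impact
pWK_PhJ	casp12	E217K	potential_impact
pWK_PhJ	casp12	N311S	unlikely
sPRET_EiJ	casp1	R33K	unlikely
sPRET_EiJ	casp11	E163Q	unlikely
sPRET_EiJ	casp12	A3V	unlikely
sPRET_EiJ	casp12	D24N	unlikely
sPRET_EiJ	casp12	L137I	unlikely
sPRET_EiJ	casp12	Q230H	unlikely
sPRET_EiJ	casp12	H270R	unlikely
sPRET_EiJ	casp12	N311S	unlikely
wSB_EiJ	casp12	I15L	potential_impact
wSB_EiJ	casp12	E46D	potential_impact
wSB_EiJ	casp12	P105L	potential_impact
aKR_J	casp12	I15L	potential_impact
aKR_J	casp12	E46D	potential_impact
aKR_J	casp12	P105L	potential_impact
cBA_J	casp11	N152K	potential_impact
cBA_J	casp12	E46D	potential_impact
nOD_ShiLtJ	casp11	H305C	potential_impact
IP_J	casp11	E126K	potential_impact
bALB_cJ	none	none	none
c57BL_6NJ	none	none	none
a_J	none	none	none
nZO_HILtJ	none	none	none
fVB_NJ	none	none	none
dBA_2J	none	none	none
c3H_HeJ	none	none	none
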