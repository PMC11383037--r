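# Synthetic stand-in for the per-species gene status table (the published
# supplementary table is not redistributed here). Statuses transcribe the
# published prose: CASP12 is intact in orangutan, Old World monkeys, loris,
# lemurs and tarsier, and degraded in the other primate lineages (implying
# at least four independent loss events); CASP4 is present across all
# simian primates and absent outside them (dating the caspase-4/5
# duplication to the simian stem branch).
# Encoding: 1 = present, 0 = pseudogene, -1 = absent, * = partial in-frame.
species	CASP12	CASP4
Homo_sapiens	0	1
Pan_troglodytes	0	1
Pan_paniscus	0	1
Gorilla_gorilla	0	1
Pongo_abelii	1	1
Nomascus_leucogenys	0	1
Macaca_mulatta	1	1
Papio_anubis	1	1
Chlorocebus_sabaeus	1	1
Colobus_angolensis	1	1
Callithrix_jacchus	0	1
Saimiri_boliviensis	-1	1
Cebus_imitator	0	1
Aotus_nancymaae	0	1
Carlito_syrichta	1	-1
Nycticebus_coucang	1	-1
Otolemur_garnettii	0	-1
Microcebus_murinus	1	-1
Lemur_catta	1	-1
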