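# Synthetic stand-in for the per-species gene status table (the published
# supplementary table is not redistributed here). Casp12 is retained across
# most rodents with up to six independent, lineage-specific pseudogenization
# and/or loss events, per the published prose; the six degraded lineages
# here are scattered so that no two are sister taxa.
# Encoding: 1 = present, 0 = pseudogene, -1 = absent, * = partial in-frame.
species	Casp12
Mus_musculus	1
Mus_spretus	1
Mus_caroli	1
Mus_pahari	1
Apodemus_sylvaticus	0
Arvicanthis_niloticus	1
Rattus_norvegicus	1
Acomys_cahirinus	1
Meriones_unguiculatus	1
Mesocricetus_auratus	0
Cricetulus_griseus	1
Microtus_ochrogaster	-1
Peromyscus_maniculatus	1
Jaculus_jaculus	1
Dipodomys_ordii	0
Ictidomys_tridecemlineatus	1
Marmota_marmota	0
Castor_canadensis	1
Cavia_porcellus	1
Octodon_degus	1
Chinchilla_lanigera	0
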