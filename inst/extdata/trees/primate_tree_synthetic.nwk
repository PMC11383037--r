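((((((((Homo_sapiens:0.007,(Pan_troglodytes:0.003,Pan_paniscus:0.003)Pan:0.004)HomoPan:0.002,Gorilla_gorilla:0.009)Homininae:0.007,Pongo_abelii:0.016)Hominidae:0.004,Nomascus_leucogenys:0.02)Hominoidea:0.01,((Macaca_mulatta:0.01,Papio_anubis:0.01)Papionini:0.005,(Chlorocebus_sabaeus:0.012,Colobus_angolensis:0.012)ColChl:0.003)Cercopithecidae:0.015)Catarrhini:0.013,((Callithrix_jacchus:0.02,Saimiri_boliviensis:0.02)CalSai:0.005,(Cebus_imitator:0.02,Aotus_nancymaae:0.02)CebAot:0.005)Platyrrhini:0.018)Simiiformes:0.026,Carlito_syrichta:0.069)Haplorhini:0.005,((Nycticebus_coucang:0.035,Otolemur_garnettii:0.035)Lorisiformes:0.025,(Microcebus_murinus:0.04,Lemur_catta:0.04)Lemuriformes:0.02)Strepsirrhini:0.014)Primates;
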