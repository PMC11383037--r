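((((((((((Mus_musculus:0.01,Mus_spretus:0.01)Mus1:0.01,Mus_caroli:0.02)Mus2:0.01,Mus_pahari:0.03)Mus:0.02,(Apodemus_sylvaticus:0.04,Arvicanthis_niloticus:0.04)ApoArv:0.01)Murinae1:0.01,Rattus_norvegicus:0.06)Murinae:0.02,(Acomys_cahirinus:0.07,Meriones_unguiculatus:0.07)AcoMer:0.01)Muridae:0.03,((Mesocricetus_auratus:0.05,Cricetulus_griseus:0.05)Cricetinae:0.03,(Microtus_ochrogaster:0.06,Peromyscus_maniculatus:0.06)ArvNeo:0.02)Cricetidae:0.03)Muroidea:0.04,(Jaculus_jaculus:0.12,Dipodomys_ordii:0.12)Dipodoidea:0.03)Myomorpha:0.03,((Ictidomys_tridecemlineatus:0.08,Marmota_marmota:0.08)Sciuridae:0.05,Castor_canadensis:0.13)SciCas:0.05)MyoSci:0.02,((Cavia_porcellus:0.1,Octodon_degus:0.1)CavOct:0.04,Chinchilla_lanigera:0.14)Hystricomorpha:0.06)Rodentia;
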