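node	age_mya
Primates	74
Haplorhini	69
Strepsirrhini	60
Simiiformes	43
Catarrhini	30
Platyrrhini	22
Hominoidea	20
Hominidae	16
Homininae	9
HomoPan	7
Pan	3
Cercopithecidae	15
Papionini	10
ColChl	12
CalSai	18
CebAot	18
Lorisiformes	38
Lemuriformes	37
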