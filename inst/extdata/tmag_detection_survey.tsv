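# Species-specific PCR detection survey of Tuber magnatum in plant root
# samples from three natural fruiting sites (spring 2022/2023):
# CDP = Citta della Pieve, PF = Panfilia Forest, MNS = Montefalcone nel Sannio.
# Per-species analyzed counts follow the study's per-species report; the
# "other_species" rows pool the remaining species collected at each site
# (all PCR-negative) so that site totals are 60/30/10 analyzed.
# Primula vulgaris analyzed count (9) and Urtica dioica analyzed count (3)
# are reconciled from family-level sample counts; both reproduce the
# reported per-species percentages (33%, 67%) under round-half-up.
site	species	n_analyzed	n_positive
CDP	Arum italicum	6	2
CDP	Sison amomum	2	1
CDP	Taraxacum dissectum	2	1
CDP	Galium verrucosum	1	1
CDP	Hedera helix	7	3
CDP	Primula vulgaris	9	3
CDP	Ranunculus bulbosus	4	1
CDP	Urtica dioica	3	2
CDP	Viola odorata	3	1
CDP	other_species	23	0
PF	Acer campestre	1	1
PF	Carex pendula	12	4
PF	other_species	17	0
MNS	Ajuga reptans	2	1
MNS	other_species	8	0
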