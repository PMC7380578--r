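#fluxtherm-model v1
@model ct_core
@variant with-malic-enzyme
# Reconstructed reduced Clostridium thermocellum-style central network:
# PPi-dependent Pfk, no pyruvate kinase; PEP reaches pyruvate via Ppdk or
# the malate shunt (Pepck, Mdh, malic enzyme).  Intracellular CO2 exchanges
# with an extracellular naturally labeled pool through the reversible co2x
# dilution reaction; ethanol formation (adhe) is reversible.
@met GLC.ext 6 0 0 0
@met G6P 6 0 0 1
@met F6P 6 0 0 1
@met FBP 6 0 0 1
@met DHAP 3 0 0 1
@met GAP 3 0 0 1
@met BPG 3 0 0 1
@met PG3 3 0 0 1
@met PEP 3 0 0 1
@met PYR 3 0 0 1
@met OAA 4 0 0 1
@met MAL 4 0 0 1
@met ACA 2 0 0 1
@met CO2 1 0 0 1
@met CO2.ext 1 0 0 0
@met ETOH.ext 2 0 0 0
@met ACE.ext 2 0 0 0
@measure G6P F6P FBP DHAP PG3 PEP PYR MAL OAA ACA
glct	GLC.ext (abcdef)	G6P (abcdef)	0	0	200	transport
pgi	G6P (abcdef)	F6P (abcdef)	1	-1000	1000	internal
pfk	F6P (abcdef)	FBP (abcdef)	1	-1000	1000	internal
fba	FBP (abcdef)	DHAP (cba) + GAP (def)	1	-1000	1000	internal
tpi	DHAP (abc)	GAP (abc)	1	-1000	1000	internal
gapdh	GAP (abc)	BPG (abc)	1	-1000	1000	internal
pgk	BPG (abc)	PG3 (abc)	1	-1000	1000	internal
eno	PG3 (abc)	PEP (abc)	1	-1000	1000	internal
ppdk	PEP (abc)	PYR (abc)	1	-1000	1000	internal
pepck	PEP (abc) + CO2 (d)	OAA (abcd)	1	-1000	1000	internal
mdh	OAA (abcd)	MAL (abcd)	1	-1000	1000	internal
mae	MAL (abcd)	PYR (abc) + CO2 (d)	0	0	1000	internal
pfor	PYR (abc)	ACA (bc) + CO2 (a)	0	0	1000	internal
adhe	ACA (ab)	ETOH.ext (ab)	1	-1000	1000	transport
ack	ACA (ab)	ACE.ext (ab)	0	0	1000	transport
co2x	CO2 (a)	CO2.ext (a)	1	-1000	1000	dilution
bm_g6p	G6P (abcdef)	-	0	0	100	biomass
bm_pg3	PG3 (abc)	-	0	0	100	biomass
bm_oaa	OAA (abcd)	-	0	0	100	biomass
bm_pyr	PYR (abc)	-	0	0	100	biomass
bm_aca	ACA (ab)	-	0	0	100	biomass
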