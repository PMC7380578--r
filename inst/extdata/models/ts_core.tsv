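#fluxtherm-model v1
@model ts_core
@variant citramalate-sbp
# Reconstructed reduced Thermoanaerobacterium saccharolyticum-style central
# network: ATP-dependent Pfk plus pyruvate kinase, a bifurcated TCA cycle
# (oxidative to AKG, reductive to succinate via symmetric fumarate), the
# non-oxidative PPP fed through the sedoheptulose-1,7-bisphosphate (SBP)
# bypass in place of transaldolase, and isoleucine synthesis via the
# citramalate route.
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
@met ACA 2 0 0 1
@met OAA 4 0 0 1
@met MAL 4 0 0 1
@met FUM 4 0 1 1
@met SUC 4 0 1 1
@met CIT 6 0 0 1
@met AKG 5 0 0 1
@met Ru5P 5 0 0 1
@met X5P 5 0 0 1
@met R5P 5 0 0 1
@met E4P 4 0 0 1
@met S7P 7 0 0 1
@met SBP 7 0 0 1
@met OBUT 4 0 0 1
@met ILE 6 0 0 1
@met CO2 1 0 0 1
@met CO2.ext 1 0 0 0
@met ETOH.ext 2 0 0 0
@met ACE.ext 2 0 0 0
@met LAC.ext 3 0 0 0
@measure G6P F6P FBP DHAP PG3 PEP PYR ACA MAL SUC AKG R5P S7P ILE
glct	GLC.ext (abcdef)	G6P (abcdef)	0	0	200	transport
pgi	G6P (abcdef)	F6P (abcdef)	1	-1000	1000	internal
pfk	F6P (abcdef)	FBP (abcdef)	1	-1000	1000	internal
fba	FBP (abcdef)	DHAP (cba) + GAP (def)	1	-1000	1000	internal
tpi	DHAP (abc)	GAP (abc)	1	-1000	1000	internal
gapdh	GAP (abc)	BPG (abc)	1	-1000	1000	internal
pgk	BPG (abc)	PG3 (abc)	1	-1000	1000	internal
eno	PG3 (abc)	PEP (abc)	1	-1000	1000	internal
pyk	PEP (abc)	PYR (abc)	0	0	1000	internal
ldh	PYR (abc)	LAC.ext (abc)	0	0	1000	transport
pfor	PYR (abc)	ACA (bc) + CO2 (a)	0	0	1000	internal
adhe	ACA (ab)	ETOH.ext (ab)	1	-1000	1000	transport
ack	ACA (ab)	ACE.ext (ab)	0	0	1000	transport
ppc	PEP (abc) + CO2 (d)	OAA (abcd)	1	-1000	1000	internal
mdh	OAA (abcd)	MAL (abcd)	1	-1000	1000	internal
fum	MAL (abcd)	FUM (abcd)	1	-1000	1000	internal
frd	FUM (abcd)	SUC (abcd)	0	0	1000	internal
cs	OAA (abcd) + ACA (ef)	CIT (dcbfea)	0	0	1000	internal
idh	CIT (abcdef)	AKG (abcde) + CO2 (f)	0	0	1000	internal
rpe	Ru5P (abcde)	X5P (abcde)	1	-1000	1000	internal
rpi	Ru5P (abcde)	R5P (abcde)	1	-1000	1000	internal
tkt1	X5P (abcde) + R5P (fghij)	S7P (abfghij) + GAP (cde)	1	-1000	1000	internal
tkt2	X5P (abcde) + E4P (fghi)	F6P (abfghi) + GAP (cde)	1	-1000	1000	internal
sba	DHAP (abc) + E4P (defg)	SBP (cbadefg)	1	-1000	1000	internal
sbpase	SBP (abcdefg)	S7P (abcdefg)	0	0	1000	internal
cima	PYR (abc) + ACA (de)	OBUT (bcde) + CO2 (a)	0	0	1000	internal
iles	OBUT (abcd) + PYR (efg)	ILE (abcdfg) + CO2 (e)	0	0	1000	internal
co2x	CO2 (a)	CO2.ext (a)	1	-1000	1000	dilution
bm_g6p	G6P (abcdef)	-	0	0	100	biomass
bm_pg3	PG3 (abc)	-	0	0	100	biomass
bm_oaa	OAA (abcd)	-	0	0	100	biomass
bm_pyr	PYR (abc)	-	0	0	100	biomass
bm_aca	ACA (ab)	-	0	0	100	biomass
bm_akg	AKG (abcde)	-	0	0	100	biomass
bm_suc	SUC (abcd)	-	0	0	100	biomass
bm_r5p	R5P (abcde)	-	0	0	100	biomass
bm_e4p	E4P (abcd)	-	0	0	100	biomass
bm_ile	ILE (abcdef)	-	0	0	100	biomass
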