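#fluxtherm-model v1
@model emp_oxppp
@variant emp-plus-oxppp
# EMP plus the oxidative pentose phosphate pathway with the canonical
# non-oxidative rearrangements (transketolase/transaldolase).
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
@met PG6 6 0 0 1
@met Ru5P 5 0 0 1
@met X5P 5 0 0 1
@met R5P 5 0 0 1
@met S7P 7 0 0 1
@met E4P 4 0 0 1
@met CO2 1 0 0 1
@met CO2.ext 1 0 0 0
@met PYR.ext 3 0 0 0
@measure G6P F6P FBP PG3 PEP PYR R5P S7P
glct	GLC.ext (abcdef)	G6P (abcdef)	0	0	1000	transport
pgi	G6P (abcdef)	F6P (abcdef)	1	-1000	1000	internal
pfk	F6P (abcdef)	FBP (abcdef)	1	-1000	1000	internal
fba	FBP (abcdef)	DHAP (cba) + GAP (def)	1	-1000	1000	internal
tpi	DHAP (abc)	GAP (abc)	1	-1000	1000	internal
g6pd	G6P (abcdef)	PG6 (abcdef)	0	0	1000	internal
gnd	PG6 (abcdef)	Ru5P (bcdef) + CO2 (a)	0	0	1000	internal
rpe	Ru5P (abcde)	X5P (abcde)	1	-1000	1000	internal
rpi	Ru5P (abcde)	R5P (abcde)	1	-1000	1000	internal
tkt1	X5P (abcde) + R5P (fghij)	S7P (abfghij) + GAP (cde)	1	-1000	1000	internal
tal	S7P (abcdefg) + GAP (hij)	F6P (abchij) + E4P (defg)	1	-1000	1000	internal
tkt2	X5P (abcde) + E4P (fghi)	F6P (abfghi) + GAP (cde)	1	-1000	1000	internal
gapdh	GAP (abc)	BPG (abc)	1	-1000	1000	internal
pgk	BPG (abc)	PG3 (abc)	1	-1000	1000	internal
eno	PG3 (abc)	PEP (abc)	1	-1000	1000	internal
pyk	PEP (abc)	PYR (abc)	0	0	1000	internal
pyrx	PYR (abc)	PYR.ext (abc)	0	0	1000	transport
co2x	CO2 (a)	CO2.ext (a)	1	-1000	1000	dilution
bm_r5p	R5P (abcde)	-	0	0	100	biomass
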