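#fluxtherm-model v1
@model emp
@variant emp-only
# Reconstructed Embden-Meyerhof-Parnas toy network (glucose -> excreted
# pyruvate); carbon-only atom maps, carbonyl-proximal carbon numbering.
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
@met PYR.ext 3 0 0 0
@measure G6P F6P FBP DHAP GAP PG3 PEP PYR
glct	GLC.ext (abcdef)	G6P (abcdef)	0	0	1000	transport
pgi	G6P (abcdef)	F6P (abcdef)	1	-1000	1000	internal
pfk	F6P (abcdef)	FBP (abcdef)	1	-1000	1000	internal
fba	FBP (abcdef)	DHAP (cba) + GAP (def)	1	-1000	1000	internal
tpi	DHAP (abc)	GAP (abc)	1	-1000	1000	internal
gapdh	GAP (abc)	BPG (abc)	1	-1000	1000	internal
pgk	BPG (abc)	PG3 (abc)	1	-1000	1000	internal
eno	PG3 (abc)	PEP (abc)	1	-1000	1000	internal
pyk	PEP (abc)	PYR (abc)	0	0	1000	internal
pyrx	PYR (abc)	PYR.ext (abc)	0	0	1000	transport
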