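#fluxtherm-model v1
@model emp_h
@variant deuterium-tracking
# EMP glycolysis tracking the glucose C4- and C5-bound hydrogens (atom order:
# carbons 1-6, then H4, H5).  The NAD(H) hydride is a one-atom balanced pool:
# GAPDH transfers the GAP C1 hydrogen to NADH, reverse GAPDH draws a hydride
# back from the pool; other dehydrogenases feed the pool with unlabeled
# hydride (HX) and drain it (nadhu).  Solvent-derived hydrogens come from the
# infinite WATER pool; hydrogens lost to solvent map onto WATER products.
@met GLC.ext 6 2 0 0
@met G6P 6 2 0 1
@met F6P 6 2 0 1
@met FBP 6 2 0 1
@met DHAP 3 1 0 1
@met GAP 3 2 0 1
@met BPG 3 1 0 1
@met PG3 3 1 0 1
@met PEP 3 0 0 1
@met PYR 3 0 0 1
@met NADH 0 1 0 1
@met WATER 0 1 0 0
@met HX 0 1 0 0
@met PYR.ext 3 0 0 0
@measure G6P F6P FBP DHAP GAP PG3 PEP NADH
glct	GLC.ext (abcdefgh)	G6P (abcdefgh)	0	0	1000	transport
pgi	G6P (abcdefgh)	F6P (abcdefgh)	1	-1000	1000	internal
pfk	F6P (abcdefgh)	FBP (abcdefgh)	1	-1000	1000	internal
fba	FBP (abcdefgh) + WATER (i)	DHAP (cbai) + GAP (defgh)	1	-1000	1000	internal
tpi	DHAP (abcd) + WATER (e)	GAP (abcde)	1	-1000	1000	internal
gapdh	GAP (abcde)	BPG (abce) + NADH (d)	1	-1000	1000	internal
pgk	BPG (abcd)	PG3 (abcd)	1	-1000	1000	internal
eno	PG3 (abcd)	PEP (abc) + WATER (d)	1	-1000	1000	internal
pyk	PEP (abc)	PYR (abc)	0	0	1000	internal
pyrx	PYR (abc)	PYR.ext (abc)	0	0	1000	transport
nadhs	HX (a)	NADH (a)	0	0	1000	dilution
nadhu	NADH (a)	-	0	0	1000	internal
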