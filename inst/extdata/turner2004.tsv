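# version: turner2004
# Turner 2004 nearest-neighbor free energies, kcal/mol at 37 C.
# Step key XY/WZ denotes the duplex 5'-X Y-3' / 3'-W Z-5' (pairs X.W, Y.Z).
# WC-WC steps carry the exact two-decimal NNDB values; steps involving a
# GU wobble carry the one-decimal Turner 2004 values (ViennaRNA release).
# flush_coax: flush coaxial stack scored as the equivalent helical step
# (Walter-Turner convention).
# mismatch_coax: mismatch-mediated (L0 = 1) interface stack, approximated
# by the helical step of the two closing pairs; the fixed 2.1 kcal/mol
# terminal-mismatch penalty is added separately by the energy function.
# general constants: duplex initiation, AU/GU terminal end penalty,
# self-complementary symmetry correction, and the empirical loop-length
# penalty constants a, b, c of the coaxial stacking function.
section	key	value
general	init	4.09
general	au_end	0.45
general	sym	0.43
general	mismatch_penalty	2.10
general	coax_a	9.30
general	coax_b	0.00
general	coax_c	-0.60
stack	CG/GC	-2.36
stack	CC/GG	-3.26
stack	CU/GG	-2.10
stack	CG/GU	-1.40
stack	CU/GA	-2.08
stack	CA/GU	-2.11
stack	GG/CC	-3.26
stack	GC/CG	-3.42
stack	GU/CG	-2.50
stack	GG/CU	-1.50
stack	GU/CA	-2.24
stack	GA/CU	-2.35
stack	GG/UC	-2.10
stack	GC/UG	-2.50
stack	GU/UG	1.30
stack	GG/UU	-0.50
stack	GU/UA	-1.40
stack	GA/UU	-1.30
stack	UG/GC	-1.40
stack	UC/GG	-1.50
stack	UU/GG	-0.50
stack	UG/GU	0.30
stack	UU/GA	-0.60
stack	UA/GU	-1.00
stack	AG/UC	-2.08
stack	AC/UG	-2.24
stack	AU/UG	-1.40
stack	AG/UU	-0.60
stack	AU/UA	-1.10
stack	AA/UU	-0.93
stack	UG/AC	-2.11
stack	UC/AG	-2.35
stack	UU/AG	-1.30
stack	UG/AU	-1.00
stack	UU/AA	-0.93
stack	UA/AU	-1.33
flush_coax	CG/GC	-2.36
flush_coax	CC/GG	-3.26
flush_coax	CU/GG	-2.10
flush_coax	CG/GU	-1.40
flush_coax	CU/GA	-2.08
flush_coax	CA/GU	-2.11
flush_coax	GG/CC	-3.26
flush_coax	GC/CG	-3.42
flush_coax	GU/CG	-2.50
flush_coax	GG/CU	-1.50
flush_coax	GU/CA	-2.24
flush_coax	GA/CU	-2.35
flush_coax	GG/UC	-2.10
flush_coax	GC/UG	-2.50
flush_coax	GU/UG	1.30
flush_coax	GG/UU	-0.50
flush_coax	GU/UA	-1.40
flush_coax	GA/UU	-1.30
flush_coax	UG/GC	-1.40
flush_coax	UC/GG	-1.50
flush_coax	UU/GG	-0.50
flush_coax	UG/GU	0.30
flush_coax	UU/GA	-0.60
flush_coax	UA/GU	-1.00
flush_coax	AG/UC	-2.08
flush_coax	AC/UG	-2.24
flush_coax	AU/UG	-1.40
flush_coax	AG/UU	-0.60
flush_coax	AU/UA	-1.10
flush_coax	AA/UU	-0.93
flush_coax	UG/AC	-2.11
flush_coax	UC/AG	-2.35
flush_coax	UU/AG	-1.30
flush_coax	UG/AU	-1.00
flush_coax	UU/AA	-0.93
flush_coax	UA/AU	-1.33
mismatch_coax	CG/GC	-2.36
mismatch_coax	CC/GG	-3.26
mismatch_coax	CU/GG	-2.10
mismatch_coax	CG/GU	-1.40
mismatch_coax	CU/GA	-2.08
mismatch_coax	CA/GU	-2.11
mismatch_coax	GG/CC	-3.26
mismatch_coax	GC/CG	-3.42
mismatch_coax	GU/CG	-2.50
mismatch_coax	GG/CU	-1.50
mismatch_coax	GU/CA	-2.24
mismatch_coax	GA/CU	-2.35
mismatch_coax	GG/UC	-2.10
mismatch_coax	GC/UG	-2.50
mismatch_coax	GU/UG	1.30
mismatch_coax	GG/UU	-0.50
mismatch_coax	GU/UA	-1.40
mismatch_coax	GA/UU	-1.30
mismatch_coax	UG/GC	-1.40
mismatch_coax	UC/GG	-1.50
mismatch_coax	UU/GG	-0.50
mismatch_coax	UG/GU	0.30
mismatch_coax	UU/GA	-0.60
mismatch_coax	UA/GU	-1.00
mismatch_coax	AG/UC	-2.08
mismatch_coax	AC/UG	-2.24
mismatch_coax	AU/UG	-1.40
mismatch_coax	AG/UU	-0.60
mismatch_coax	AU/UA	-1.10
mismatch_coax	AA/UU	-0.93
mismatch_coax	UG/AC	-2.11
mismatch_coax	UC/AG	-2.35
mismatch_coax	UU/AG	-1.30
mismatch_coax	UG/AU	-1.00
mismatch_coax	UU/AA	-0.93
mismatch_coax	UA/AU	-1.33
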