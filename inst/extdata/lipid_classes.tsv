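# Lipid class construction rules. version: 1
# The formula of an all-acyl species with total side-chain carbons n and total
# side-chain double bonds d is: base + n*C + (2n - 2d)*H.
# Ether ([O]) species: the diacyl counterpart - O + 2 H (alkyl sn-1 linkage;
# plasmenyl species are represented as alkyl with the vinyl-ether double bond
# counted in double_bonds).
# columns: class	n_chains	C	H	N	O	P	min_carbons	ether_allowed	polarity	adduct
class	n_chains	C	H	N	O	P	min_carbons	ether_allowed	polarity	adduct
PC	2	8	16	1	8	1	4	yes	positive	[M+H]+
PE	2	5	10	1	8	1	4	yes	negative	[M-H]-
PS	2	6	10	1	10	1	4	yes	negative	[M-H]-
PI	2	9	15	0	13	1	4	no	negative	[M-H]-
PG	2	6	11	0	10	1	4	no	negative	[M-H]-
PA	2	3	5	0	8	1	4	no	negative	[M-H]-
BMP	2	6	11	0	10	1	4	no	negative	[M-H]-
CL	4	9	14	0	17	2	8	no	negative	[M-H]-
SM	2	5	13	2	6	1	14	no	positive	[M+H]+
Cer	2	0	1	1	3	0	14	no	positive	[M+H]+
LPC	1	8	18	1	7	1	2	yes	positive	[M+H]+
LPE	1	5	12	1	7	1	2	yes	negative	[M-H]-
LPG	1	6	13	0	9	1	2	no	negative	[M-H]-
LPA	1	3	7	0	7	1	2	no	negative	[M-H]-
DG	2	3	4	0	5	0	4	yes	positive	[M+NH4]+
TG	3	3	2	0	6	0	6	yes	positive	[M+NH4]+
CE	1	27	44	0	2	0	2	no	positive	[M+NH4]+
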