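# Internal-standard panel: synthetic short-chain species spiked per extraction
# (amounts in nmol per extraction of 1 mg protein). version: 1
# columns: class	carbons	double_bonds	nmol
class	carbons	double_bonds	nmol
CL	56	0	0.1
BMP	28	0	0.2
PC	28	0	2.0
PG	28	0	0.1
PS	28	0	5.0
PE	28	0	0.5
PA	28	0	0.5
SM	30	1	2.125
LPG	14	0	0.02
LPE	14	0	0.1
LPC	14	0	0.5
LPA	14	0	0.1
PI	16	0	0.5
DG	28	0	0.5
TG	42	0	0.5
CE	16	0	2.5
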