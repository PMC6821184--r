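# Electrospray adducts. mass_delta in Da (includes electron mass). version: 1
# columns: label	polarity	mass_delta	charge
label	polarity	mass_delta	charge
[M+H]+	positive	1.00727646688	1
[M+NH4]+	positive	18.03382555	1
[M+Na]+	positive	22.98922142	1
[M-H]-	negative	-1.00727646688	1
[M+HCOO]-	negative	44.99820285	1
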