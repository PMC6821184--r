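# Stable-isotope monoisotopic masses (Da) and natural abundances (fraction).
# Source: IUPAC-CIAAW 2021 representative values. version: 1
# columns: element	nucleons	mass	abundance
element	nucleons	mass	abundance
C	12	12.0	0.9893
C	13	13.003354835	0.0107
H	1	1.0078250319	0.999885
H	2	2.0141017781	0.000115
N	14	14.0030740052	0.99636
N	15	15.0001088984	0.00364
O	16	15.9949146221	0.99757
O	17	16.9991315	0.00038
O	18	17.9991604	0.00205
P	31	30.97376151	1.0
S	32	31.97207069	0.9499
S	33	32.9714585	0.0075
S	34	33.96786683	0.0425
S	36	35.96708088	0.0001
Na	23	22.98976928	1.0
K	39	38.9637069	0.932581
K	40	39.96399867	0.000117
K	41	40.96182597	0.067302
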