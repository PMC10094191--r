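codon	aa	count	rscu_printed	preferred
UUU	F	105	0.58	TRUE
UUC	F	221	1.42	FALSE
UUA	L	28	0.63	TRUE
UUG	L	57	1.14	TRUE
CUU	L	47	1.03	TRUE
CUC	L	68	1.42	FALSE
CUA	L	21	0.43	FALSE
CUG	L	67	1.36	FALSE
AUU	I	76	0.94	TRUE
AUC	I	89	1.55	FALSE
AUA	I	42	0.51	TRUE
GUU	V	67	0.96	TRUE
GUC	V	60	0.94	FALSE
GUA	V	38	0.60	TRUE
GUG	V	113	1.50	FALSE
UCU	S	73	1.24	TRUE
UCC	S	68	1.44	FALSE
UCA	S	49	0.87	FALSE
UCG	S	42	0.72	FALSE
AGU	S	39	0.77	TRUE
AGC	S	51	0.96	FALSE
CCU	P	56	0.85	TRUE
CCC	P	58	1.03	FALSE
CCA	P	76	1.19	TRUE
CCG	P	49	0.93	FALSE
ACU	T	84	1.24	TRUE
ACC	T	74	1.17	FALSE
ACA	T	69	1.02	TRUE
ACG	T	36	0.57	FALSE
GCU	A	106	1.42	TRUE
GCC	A	104	1.40	FALSE
GCA	A	50	0.64	TRUE
GCG	A	48	0.54	TRUE
UAU	Y	73	0.54	TRUE
UAC	Y	182	1.46	FALSE
CAU	H	44	0.83	TRUE
CAC	H	58	1.18	FALSE
CAA	Q	85	0.82	TRUE
CAG	Q	132	1.18	FALSE
AAU	N	66	0.62	TRUE
AAC	N	132	1.38	FALSE
AAA	K	99	0.71	TRUE
AAG	K	146	1.29	FALSE
GAU	D	153	0.86	TRUE
GAC	D	183	1.14	FALSE
GAA	E	59	0.62	TRUE
GAG	E	115	1.38	FALSE
UGU	C	32	0.64	TRUE
UGC	C	47	1.06	FALSE
CGU	R	25	0.45	TRUE
CGC	R	51	0.92	FALSE
CGA	R	22	0.39	TRUE
CGG	R	30	0.61	FALSE
AGA	R	86	1.89	TRUE
AGG	R	84	1.74	TRUE
GGU	G	77	0.97	TRUE
GGC	G	112	1.06	FALSE
GGA	G	99	1.15	TRUE
GGG	G	77	0.82	FALSE
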