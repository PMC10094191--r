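codon	aa	count	rscu_printed	preferred
UUU	F	13	0.90	TRUE
UUC	F	16	1.10	FALSE
UUA	L	0	0.00	TRUE
UUG	L	5	1.50	TRUE
CUU	L	8	2.40	TRUE
CUC	L	2	0.60	FALSE
CUA	L	0	0.00	FALSE
CUG	L	5	1.50	FALSE
AUU	I	9	1.59	TRUE
AUC	I	3	0.53	FALSE
AUA	I	5	0.88	TRUE
GUU	V	7	1.65	TRUE
GUC	V	3	0.71	FALSE
GUA	V	1	0.24	TRUE
GUG	V	6	1.41	FALSE
UCU	S	7	2.10	TRUE
UCC	S	2	0.60	FALSE
UCA	S	6	1.80	FALSE
UCG	S	1	0.30	FALSE
AGU	S	4	1.20	TRUE
AGC	S	0	0.00	FALSE
CCU	P	5	1.33	TRUE
CCC	P	1	0.27	FALSE
CCA	P	7	1.87	TRUE
CCG	P	2	0.53	FALSE
ACU	T	6	1.50	TRUE
ACC	T	2	0.50	FALSE
ACA	T	6	1.50	TRUE
ACG	T	2	0.50	FALSE
GCU	A	10	2.67	TRUE
GCC	A	3	0.80	FALSE
GCA	A	1	0.27	TRUE
GCG	A	1	0.27	TRUE
UAU	Y	3	0.35	TRUE
UAC	Y	14	1.65	FALSE
CAU	H	4	1.33	TRUE
CAC	H	2	0.67	FALSE
CAA	Q	6	0.86	TRUE
CAG	Q	8	1.14	FALSE
AAU	N	8	1.33	TRUE
AAC	N	4	0.67	FALSE
AAA	K	17	1.62	TRUE
AAG	K	4	0.38	FALSE
GAU	D	16	1.45	TRUE
GAC	D	6	0.55	FALSE
GAA	E	6	1.09	TRUE
GAG	E	5	0.91	FALSE
UGU	C	4	1.30	TRUE
UGC	C	2	0.70	FALSE
CGU	R	3	0.90	TRUE
CGC	R	2	0.60	FALSE
CGA	R	1	0.30	TRUE
CGG	R	0	0.00	FALSE
AGA	R	13	3.90	TRUE
AGG	R	1	0.30	TRUE
GGU	G	4	0.70	TRUE
GGC	G	8	1.50	FALSE
GGA	G	7	1.30	TRUE
GGG	G	3	0.60	FALSE
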