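codon	amino_acid	pbcv1	an69c	host	ratio_printed	recognized
GCA	A	1.92	1.15	2.42	0.63	FALSE
GCC	A	0.86	0.64	5.54	0.14	FALSE
GCG	A	1.29	0.84	5.46	0.2	FALSE
GCU	A	1.3	0.82	1.72	0.62	FALSE
UGC	C	0.67	1.08	1.77	0.49	FALSE
UGU	C	1.23	1.88	0.32	4.86	FALSE
GAC	D	1.97	1.31	3.04	0.54	FALSE
GAU	D	3.02	1.91	1.06	4.56	FALSE
GAA	E	3.69	2.47	0.54	5.7	FALSE
GAG	E	1.26	1.08	4.92	0.24	FALSE
UUC	F	2.53	2.4	1.55	1.59	FALSE
UUU	F	2.94	3.49	0.95	3.38	FALSE
GGA	G	1.71	1.28	0.76	1.97	TRUE
GGC	G	0.61	0.61	5.88	0.1	FALSE
GGG	G	1.12	0.92	2.07	0.52	FALSE
GGU	G	2.1	1.42	0.67	2.63	FALSE
CAC	H	0.89	1.21	1.89	0.56	FALSE
CAU	H	1.26	1.87	0.52	3.01	FALSE
AUA	I	2.44	2.64	0.2	12.7	TRUE
AUC	I	2	1.8	1.68	1.13	FALSE
AUU	I	2.87	2.88	0.44	6.53	FALSE
AAA	K	4.7	3.76	0.25	16.92	TRUE
AAG	K	2.48	1.91	2.53	0.87	TRUE
CUA	L	0.85	0.93	0.27	3.3	FALSE
CUC	L	1.26	1.09	1.47	0.8	FALSE
CUG	L	0.85	1.08	6.85	0.14	FALSE
CUU	L	1.65	1.67	0.5	2	FALSE
UUA	L	1.39	1.81	0.06	26.67	TRUE
UUG	L	1.76	2.06	0.56	3.41	TRUE
AUG	M	2.76	1.97	1.84	2.04	FALSE
AAC	N	2.62	2.28	1.48	1.66	TRUE
AAU	N	3.16	2.78	0.3	9.9	FALSE
CCA	P	1.42	1.24	1.08	1.23	FALSE
CCC	P	1.07	0.91	2.55	0.39	FALSE
CCG	P	0.96	0.97	2.3	0.42	FALSE
CCU	P	1.33	0.89	0.96	1.16	FALSE
CAA	Q	1.84	2.09	0.59	3.33	FALSE
CAG	Q	0.87	1.06	4.93	0.2	FALSE
AGA	R	1.43	1.71	0.25	6.28	TRUE
AGG	R	0.68	0.84	0.92	0.83	FALSE
CGA	R	0.66	1.48	0.44	2.43	FALSE
CGC	R	0.66	0.84	3.22	0.23	FALSE
CGG	R	0.45	0.94	2.11	0.32	FALSE
CGU	R	1.05	1.38	0.44	2.76	FALSE
AGC	S	0.71	0.82	3.03	0.25	FALSE
AGU	S	1.26	1.24	0.27	4.63	FALSE
UCA	S	1.48	1.78	0.43	3.79	FALSE
UCC	S	0.98	1.34	1.33	0.87	FALSE
UCG	S	1.1	1.38	1.05	1.18	FALSE
UCU	S	1.88	1.69	0.51	3.5	FALSE
ACA	T	2.01	1.87	0.61	3.18	FALSE
ACC	T	1.32	1.38	1.98	0.68	FALSE
ACG	T	1.62	1.57	1.29	1.24	FALSE
ACU	T	1.57	1.31	0.39	3.69	FALSE
GUA	V	1.8	1.54	0.25	6.68	FALSE
GUC	V	1.35	1.25	1.16	1.12	FALSE
GUG	V	1.57	1.37	4.23	0.35	FALSE
GUU	V	2.34	2.28	0.4	5.78	TRUE
UGG	W	1.09	1.24	1.61	0.72	FALSE
UAC	Y	1.52	1.46	1.42	1.05	TRUE
UAU	Y	2.24	2.66	0.38	6.45	FALSE
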