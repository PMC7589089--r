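virus	clade	position	amino_acid	codon	copy	spacer_after	pseudogene	intron	orphan	note	total_printed
Fr5L	Pbi	1	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	2	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	3	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	4	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	5	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	11
Fr5L	Pbi	6	Lys	AAG	1	25	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	7	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	8	Asn	AAC	3	22	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	9	Tyr	UAC	2	2	FALSE	TRUE	FALSE	NA	11
Fr5L	Pbi	10	Lys	AAG	2	245	FALSE	FALSE	FALSE	NA	11
Fr5L	Pbi	11	Thr	ACG	2	NA	FALSE	FALSE	FALSE	NA	11
CZ-2	Pbi	1	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	2	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	3	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	4	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	5	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	6	Asn	AAC	3	22	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	7	Asn	AAC	4	22	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	8	Tyr	UAC	2	2	FALSE	TRUE	FALSE	NA	10
CZ-2	Pbi	9	Lys	AAG	2	243	FALSE	FALSE	FALSE	NA	10
CZ-2	Pbi	10	Thr	ACG	2	NA	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	1	Ile	AUA	1	24	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	2	Leu	UUA	1	24	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	3	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	4	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	5	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	6	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	7	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	8	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	10
MT325	Pbi	9	Lys	AAG	1	161	FALSE	FALSE	FALSE	NA	10
MT325	Pbi	10	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	1	Ile	AUA	1	24	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	2	Leu	UUA	1	24	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	3	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	4	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	5	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	6	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	7	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	8	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	10
Can18-4	Pbi	9	Lys	AAG	1	1041	FALSE	FALSE	FALSE	NA	10
Can18-4	Pbi	10	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	1	Ile	AUA	1	24	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	2	Leu	UUA	1	24	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	3	Phe	UUC	1	26	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	4	Arg	AGA	1	985	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	5	Gly	GGA	1	24	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	6	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	7	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	8	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	10
CVB-1	Pbi	9	Lys	AAG	1	161	FALSE	FALSE	FALSE	NA	10
CVB-1	Pbi	10	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	10
FR483	Pbi	1	Ile	AUA	1	22	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	2	Leu	UUA	1	24	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	3	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	5	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	6	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	7	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
FR483	Pbi	8	Lys	AAG	1	161	FALSE	FALSE	FALSE	NA	9
FR483	Pbi	9	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	1	Ile	AUA	1	132	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	2	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	3	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	5	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	6	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	7	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
CVG-1	Pbi	8	Lys	AAG	1	161	FALSE	FALSE	FALSE	NA	9
CVG-1	Pbi	9	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	1	Ile	AUA	1	132	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	2	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	3	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	5	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	6	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	7	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
CVR-1	Pbi	8	Lys	AAG	1	159	FALSE	FALSE	FALSE	NA	9
CVR-1	Pbi	9	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	1	Ile	AUA	1	132	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	2	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	3	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	5	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	6	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	7	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
CVA-1	Pbi	8	Lys	AAG	1	159	FALSE	FALSE	FALSE	NA	9
CVA-1	Pbi	9	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	1	Ile	AUA	1	132	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	2	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	3	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	5	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	6	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	7	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
AP110A	Pbi	8	Lys	AAG	1	159	FALSE	FALSE	FALSE	NA	9
AP110A	Pbi	9	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	1	Ile	AUA	1	132	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	2	Phe	UUC	1	23	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	3	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	4	Gly	GGA	1	24	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	5	Asn	AAC	1	96	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	6	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	7	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
CVM-1	Pbi	8	Lys	AAG	1	161	FALSE	FALSE	FALSE	NA	9
CVM-1	Pbi	9	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	9
NW665.2	Pbi	1	Ile	AUA	1	1142	FALSE	FALSE	FALSE	NA	8
NW665.2	Pbi	2	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	8
NW665.2	Pbi	3	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	8
NW665.2	Pbi	4	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	8
NW665.2	Pbi	5	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	8
NW665.2	Pbi	6	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	8
NW665.2	Pbi	7	Lys	AAG	1	161	FALSE	FALSE	FALSE	NA	8
NW665.2	Pbi	8	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	8
OR0704.2.2	Pbi	1	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	7
OR0704.2.2	Pbi	2	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	7
OR0704.2.2	Pbi	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	7
OR0704.2.2	Pbi	4	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	7
OR0704.2.2	Pbi	5	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	7
OR0704.2.2	Pbi	6	Lys	AAG	1	159	FALSE	FALSE	FALSE	NA	7
OR0704.2.2	Pbi	7	Thr	ACG	1	NA	FALSE	FALSE	FALSE	NA	7
NE-JV-1	Pbi	1	Ile	AUA	1	132	FALSE	FALSE	FALSE	NA	3
NE-JV-1	Pbi	2	Arg	AGA	1	1416	FALSE	FALSE	FALSE	NA	3
NE-JV-1	Pbi	3	Asn	AAC	1	NA	FALSE	FALSE	FALSE	NA	3
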