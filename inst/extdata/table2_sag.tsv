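virus	clade	position	amino_acid	codon	copy	spacer_after	pseudogene	intron	orphan	note	total_printed
Can0610SP	SAG	1	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	4	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	5	Ile	AUU	1	25	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	6	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	7	Met	AUG	1	22	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	8	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	9	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	10	Tyr	UAC	1	21	FALSE	TRUE	FALSE	NA	13
Can0610SP	SAG	11	Lys	AAG	1	4	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	12	Asn	AAC	3	36000	FALSE	FALSE	FALSE	NA	13
Can0610SP	SAG	13	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	13
OR0704.3	SAG	1	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	4	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	5	Ile	AUU	1	25	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	6	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	7	Met	AUG	1	22	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	8	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	9	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	10	Tyr	UAC	1	21	FALSE	TRUE	FALSE	NA	13
OR0704.3	SAG	11	Lys	AAG	1	148	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	12	Asn	AAC	3	32000	FALSE	FALSE	FALSE	NA	13
OR0704.3	SAG	13	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	13
NE-JV-2	SAG	1	Ile	AUA	1	22	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	2	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	3	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	4	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	5	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	6	Ile	AUU	1	22	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	7	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	8	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	9	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	10	Tyr	UAC	1	21	FALSE	TRUE	FALSE	NA	13
NE-JV-2	SAG	11	Lys	AAG	1	148	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	12	Asn	AAC	3	29000	FALSE	FALSE	FALSE	NA	13
NE-JV-2	SAG	13	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	13
NE-JV-3	SAG	1	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	4	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	5	Ile	AUU	1	22	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	6	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	7	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	8	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	9	Tyr	UAC	1	21	FALSE	TRUE	FALSE	NA	12
NE-JV-3	SAG	10	Lys	AAG	1	148	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	11	Asn	AAC	3	31000	FALSE	FALSE	FALSE	NA	12
NE-JV-3	SAG	12	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	12
ATCV-1	SAG	1	Ser	AGU	1	5	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	5	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	6	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	7	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	8	Tyr	UAC	1	22	FALSE	TRUE	FALSE	NA	11
ATCV-1	SAG	9	Lys	AAG	1	148	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	10	Asn	AAC	3	31000	FALSE	FALSE	FALSE	NA	11
ATCV-1	SAG	11	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	11
WI0606	SAG	1	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	5	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	6	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	7	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	8	Tyr	UAC	1	22	FALSE	TRUE	FALSE	NA	11
WI0606	SAG	9	Lys	AAG	1	148	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	10	Asn	AAC	3	31000	FALSE	FALSE	FALSE	NA	11
WI0606	SAG	11	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	11
MO0605SPH	SAG	1	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	4	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	5	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	6	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	7	Val	GUU	1	2	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	8	Tyr	UAC	1	22	FALSE	TRUE	FALSE	NA	11
MO0605SPH	SAG	9	Lys	AAG	1	148	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	10	Asn	AAC	3	30000	FALSE	FALSE	FALSE	NA	11
MO0605SPH	SAG	11	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	11
GM0701.1	SAG	1	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	2	Asn	AAC	1	1	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	3	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	4	Ile	AUU	1	24	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	5	Met	AUG	1	23	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	6	Asn	AAC	2	148	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	7	Leu	UUA	1	77	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	8	Leu	UUG	1	4	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	9	Asn	AAC	3	35000	FALSE	FALSE	FALSE	NA	10
GM0701.1	SAG	10	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	10
Br0604L	SAG	1	Ser	AGU	1	4	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	4	Gly	GGA	1	25	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	5	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	6	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
Br0604L	SAG	7	Lys	AAG	1	242	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	8	Asn	AAC	3	32000	FALSE	FALSE	FALSE	NA	9
Br0604L	SAG	9	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	9
TN603.4.2	SAG	1	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	2	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	3	Gly	GGA	1	24	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	4	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	5	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	9
TN603.4.2	SAG	6	Lys	AAG	1	22	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	7	Asn	AAC	3	227	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	8	Leu	UUA	1	32000	FALSE	FALSE	FALSE	NA	9
TN603.4.2	SAG	9	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	9
Canal-1	SAG	1	Ile	AUA	1	158	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	2	Ser	AGU	1	5	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	3	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	4	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	5	Gly	GGA	1	65	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	6	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	7	Tyr	UAC	1	24	FALSE	TRUE	FALSE	NA	9
Canal-1	SAG	8	Asn	AAC	3	29000	FALSE	FALSE	FALSE	NA	9
Canal-1	SAG	9	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	9
MN0810.1	SAG	1	Ser	AGU	1	23	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	2	Arg	AGA	1	24	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	3	Asn	AAC	1	1	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	4	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	5	Asn	AAC	2	22	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	6	Asp	GAC	1	22	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	7	Val	GUU	1	4	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	8	Asn	AAC	3	35000	FALSE	FALSE	FALSE	NA	9
MN0810.1	SAG	9	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	9
NTS-1	SAG	1	Ser	AGU	1	23	FALSE	FALSE	FALSE	NA	7
NTS-1	SAG	2	Arg	AGA	1	25	FALSE	FALSE	FALSE	NA	7
NTS-1	SAG	3	Asn	AAC	1	22	FALSE	FALSE	FALSE	NA	7
NTS-1	SAG	4	Gly	GGA	1	21	FALSE	FALSE	FALSE	NA	7
NTS-1	SAG	5	Tyr	UAC	1	23	FALSE	TRUE	FALSE	NA	7
NTS-1	SAG	6	Asn	AAC	2	33000	FALSE	FALSE	FALSE	NA	7
NTS-1	SAG	7	Thr	ACU	1	NA	FALSE	FALSE	TRUE	NA	7
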