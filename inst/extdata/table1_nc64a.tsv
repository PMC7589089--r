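virus	clade	position	amino_acid	codon	copy	spacer_after	pseudogene	intron	orphan	note	total_printed
MA-1E	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	5	Arg	AGA	1	23	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	7	Gly	GGA	1	27	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	8	Asn	AAC	3	3	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	9	Lys	AAG	1	22	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	10	Gln	CAG	1	23	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	11	Lys	AAG	2	23	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	12	Tyr	UAC	1	30	FALSE	TRUE	FALSE	NA	14
MA-1E	NC64A	13	Lys	AAA	1	1	FALSE	FALSE	FALSE	NA	14
MA-1E	NC64A	14	Lys	AAG	3	NA	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	5	Arg	AGA	1	23	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	7	Gly	GGA	1	27	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	8	Asn	AAC	3	3	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	9	Lys	AAG	1	22	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	10	Gln	CAG	1	23	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	11	Lys	AAG	2	23	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	12	Tyr	UAC	1	30	FALSE	TRUE	FALSE	NA	14
CvsA1	NC64A	13	Lys	AAA	1	1	FALSE	FALSE	FALSE	NA	14
CvsA1	NC64A	14	Lys	AAG	3	NA	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	5	Arg	AGA	1	23	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	7	Gly	GGA	1	27	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	8	Asn	AAC	3	3	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	9	Lys	AAG	1	22	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	10	Gln	CAG	1	23	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	11	Lys	AAG	2	23	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	12	Tyr	UAC	1	30	FALSE	TRUE	FALSE	NA	14
CviK1	NC64A	13	Lys	AAA	1	1	FALSE	FALSE	FALSE	NA	14
CviK1	NC64A	14	Lys	AAG	3	NA	FALSE	FALSE	FALSE	NA	14
KS1B	NC64A	1	Leu	UUG	1	3	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	3	Asn	AAC	1	109	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	4	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	5	Asn	AAC	2	23	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	6	Gly	GGA	1	3	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	7	Asn	AAC	3	27	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	8	Lys	AAG	1	3	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	9	Gln	CAG	1	22	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	10	Lys	AAG	2	23	FALSE	FALSE	FALSE	NA	12
KS1B	NC64A	11	Tyr	UAC	1	23	FALSE	TRUE	FALSE	NA	12
KS1B	NC64A	12	Lys	AAA	1	NA	FALSE	FALSE	FALSE	NA	12
PBCV-1	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	3	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	5	Arg	AGA	1	24	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	7	Lys	AAG	4	24	FALSE	FALSE	FALSE	tRNA-Lys substitution for tRNA-Gly	11
PBCV-1	NC64A	8	Asn	AAC	3	22	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	9	Lys	AAG	1	23	FALSE	FALSE	FALSE	NA	11
PBCV-1	NC64A	10	Tyr	UAC	1	33	FALSE	TRUE	FALSE	NA	11
PBCV-1	NC64A	11	Lys	AAA	1	NA	FALSE	FALSE	FALSE	NA	11
IL-3A	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	5	Arg	AGA	1	23	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	7	Gly	GGA	1	25	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	8	Asn	AAC	3	3	FALSE	FALSE	FALSE	NA	10
IL-3A	NC64A	9	Asn	AAC	4	84	FALSE	FALSE	FALSE	tRNA-Asn substitution for tRNA-Gln	10
IL-3A	NC64A	10	Tyr	UAC	1	NA	FALSE	TRUE	FALSE	NA	10
MA-1D	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	4	Leu	UUA	1	5	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	5	Arg	AGA	1	15	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	7	Gly	GGA	1	25	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	8	Asn	AAC	3	3	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	9	Lys	AAG	1	22	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	10	Gln	CAG	1	23	FALSE	FALSE	FALSE	NA	12
MA-1D	NC64A	11	Tyr	UAC	1	33	FALSE	TRUE	FALSE	NA	12
MA-1D	NC64A	12	Lys	AAG	3	NA	FALSE	FALSE	FALSE	NA	12
NE-JV-4	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	5	Arg	AGA	1	23	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	7	Gly	GGA	1	72	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	8	Asn	AAC	4	3	FALSE	FALSE	FALSE	tRNA-Asn substitution for tRNA-Gln	11
NE-JV-4	NC64A	9	Lys	AAG	1	23	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	10	Lys	AAG	2	33	FALSE	FALSE	FALSE	NA	11
NE-JV-4	NC64A	11	Lys	AAG	3	NA	FALSE	FALSE	FALSE	NA	11
AN69C	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	2	Ile	AUA	1	23	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	3	Asn	AAC	1	24	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	4	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	5	Arg	AGA	1	23	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	6	Asn	AAC	2	3	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	7	Gly	GGA	1	12	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	8	Asn	AAC	3	22	FALSE	FALSE	FALSE	NA	10
AN69C	NC64A	9	Tyr	UAC	1	23	FALSE	TRUE	FALSE	NA	10
AN69C	NC64A	10	Val	GUU	1	NA	FALSE	FALSE	FALSE	NA	10
NY-2B	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	8
NY-2B	NC64A	2	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	8
NY-2B	NC64A	3	Leu	UUA	1	23	FALSE	FALSE	FALSE	NA	8
NY-2B	NC64A	4	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	8
NY-2B	NC64A	5	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	8
NY-2B	NC64A	6	Tyr	UAC	1	22	FALSE	TRUE	FALSE	NA	8
NY-2B	NC64A	7	Asp	GAC	1	2	FALSE	FALSE	FALSE	NA	8
NY-2B	NC64A	8	Val	GUU	1	NA	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	2	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	3	Leu	UUA	1	23	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	4	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	5	Gly	GGA	1	23	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	6	Tyr	UAC	1	22	FALSE	TRUE	FALSE	NA	8
IL-5-2s1	NC64A	7	Asp	GAC	1	2	FALSE	FALSE	FALSE	NA	8
IL-5-2s1	NC64A	8	Val	GUU	1	NA	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	1	Leu	UUG	1	142	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	2	Asn	AAC	1	23	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	3	Leu	UUA	1	3	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	4	Arg	AGA	1	24	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	5	Gly	GGA	1	22	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	6	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	8
NY-2A	NC64A	7	Asp	GAC	1	25	FALSE	FALSE	FALSE	NA	8
NY-2A	NC64A	8	Val	GUU	1	NA	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	2	Ile	AUA	1	25	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	3	Asn	AAC	1	229	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	4	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	5	Gly	GGA	1	1058	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	6	Tyr	UAC	1	2	FALSE	TRUE	FALSE	NA	8
NYs-1	NC64A	7	Asp	GAC	1	25	FALSE	FALSE	FALSE	NA	8
NYs-1	NC64A	8	Val	GUU	1	NA	FALSE	FALSE	FALSE	NA	8
AR158	NC64A	1	Leu	UUG	1	25	FALSE	FALSE	FALSE	NA	7
AR158	NC64A	2	Ile	AUA	1	25	FALSE	FALSE	FALSE	NA	7
AR158	NC64A	3	Asn	AAC	1	51	FALSE	FALSE	FALSE	NA	7
AR158	NC64A	4	Leu	UUA	1	23	FALSE	FALSE	FALSE	NA	7
AR158	NC64A	5	Arg	AGA	1	3	FALSE	FALSE	FALSE	NA	7
AR158	NC64A	6	Asn	AAC	2	24	FALSE	FALSE	FALSE	NA	7
AR158	NC64A	7	Gly	GGA	1	NA	FALSE	FALSE	FALSE	NA	7
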