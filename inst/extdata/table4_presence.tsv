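label	amino_acid	codon	copy	nc64a	sag	pbi
Ile-1	Ile	AUA	1	c	c	c
Leu-1	Leu	UUA	1	c	c	c
Asn-1	Asn	AAC	1	c	c	c
Gly-1	Gly	GGA	1	c	c	c
Lys-1	Lys	AAG	1	c	c	c
Tyr-1	Tyr	UAC	1	c	c	c
Arg-1	Arg	AGA	1	c	c	c
Asp-1	Asp	GAC	1	d	d	.
Val-1	Val	GUU	1	d	d	.
Leu-2	Leu	UUG	1	d	d	.
Gln-1	Gln	CAG	1	u	.	.
Lys-2	Lys	AAA	1	u	.	.
Ser-1	Ser	AGU	1	.	u	.
Ile-2	Ile	AUU	1	.	u	.
Met-1	Met	AUG	1	.	u	.
Thr-1a	Thr	ACU	1	.	u	.
Phe-1	Phe	UUC	1	.	.	u
Thr-1b	Thr	ACG	1	.	.	u
Thr-2	Thr	ACG	2	.	.	u
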