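table	item	note
table5_codon_usage	GAU	printed ratio 4.56; footnote formula gives 2.33 from the printed frequencies (2.465/1.06); printing erratum
table5_codon_usage	GGG	printed ratio 0.52; formula gives 0.49
table5_codon_usage	CUU	printed ratio 2.00; formula gives 3.32
table5_codon_usage	AUG	printed ratio 2.04; formula gives 1.29
table5_codon_usage	column sums	printed frequency columns sum to 99.42 / 95.57 / 99.64 (PBCV-1 / AN69C / host), not 100
tables1-3	pseudogene flags	the orange (pseudogene) cell coloring is not recoverable from the text transcription; all pseudogene flags are FALSE
tables1-3	column occupancy	per-virus column occupancy reconstructed from printed totals, spacer counts, footnotes (substitutions b/c, introns, orphan distances) and prose (PBCV-1 recognized-codon set, AN69C 10 genes with 8 favoring, AR158 lacks Lys-AAG, CZ-2 has four Asn-AAC, MA-1E has three Lys-AAG, tree-marker exclusion list, Arg in 41/41, Gly in 39/41)
table1_nc64a	KS1B	13 printed spacer values cannot be reconciled with the printed total of 12 genes (11 junctions); the first 11 values are kept
table1_nc64a	IL-3A	11 printed values vs 9 junctions; first 9 kept
table1_nc64a	NY-2B, IL-5-2s1	8 printed values vs 7 junctions; first 7 kept
table2_sag	ATCV-1	11 printed values vs 10 junctions; one duplicate 22 dropped
table2_sag	Canal-1	9 printed values vs 8 junctions; the 54 dropped
table3_pbi	Thr-ACG copies	the two distinct Thr-ACG gene columns (Table 4 rows Thr-1/Thr-2) are assigned copy 1 (161/159-type trailing spacer) and copy 2 (Fr5L, CZ-2; 245/243 trailing spacer)
paper	total tRNAs	abstract/prose print 410; the per-virus printed totals sum to 407 (147+137+123)
paper	distinct tRNAs	prose prints 17 different tRNAs; the union of the table headings yields 18 identities
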