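file	md5
table1_nc64a.tsv	00582d7b2ef314e7ec9f3f05a1ba1c53
table2_sag.tsv	5bdd0214b96762c10e2816f928ded695
table3_pbi.tsv	afb0846bd747df2c54fe6836e0e93807
table4_presence.tsv	1fba9cb535154849b24d975ba81f240d
table5_codon_usage.tsv	b965a3875a80e76afd6cf25f88fd59a7
fixture_errata.tsv	e9379ffac70cbf118213c5fdf95fee83
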