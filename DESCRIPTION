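Package: chlorotrna
Title: tRNA Gene Clusters and Codon Usage Bias in Chloroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for virus-encoded tRNA gene clusters and their
    role in overcoming host codon usage bias (CUB), built around the
    chlorovirus system (GC-rich chlorella-like algal hosts infected by AT-rich
    Phycodnaviridae). Reads annotated genomes (GenBank flat files or
    GFF3+FASTA), builds semantically rich tRNA inventories (anticodon-codon
    recognition with wobble rules and the TilS lysidine recoding of
    tRNA-Met, intron geometry, RNA polymerase III Box A/B promoter scans,
    CCA-tail status), detects tRNA gene clusters under strict or relaxed
    intervening-gene rules with intergenic spacer accounting and orphan
    assignment, computes per-codon usage tables and the mean-virus/host
    codon usage ratio statistic with tRNA favorability classification, and
    summarises presence/absence of tRNA identities across virus clades.
    Includes a deterministic synthetic genome generator with full ground
    truth for validation, and packaged machine-readable transcriptions of
    the published chlorovirus tRNA and codon-usage tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    tibble,
    dplyr,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
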