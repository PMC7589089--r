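---
title: "Methods: tRNA clusters and codon usage bias in chloroviruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tRNA clusters and codon usage bias in chloroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorotrna)
```

## The biological problem

Chloroviruses replicate in chlorella-like green algae whose nuclear genomes
are ~67% GC and whose coding sequences strongly prefer GC-ending codons.
The viruses themselves are AT-rich (40-50% GC) and prefer AU-ending codons,
so viral messages are enriched for exactly the codons the host decodes
worst. The viruses respond by carrying their own tRNA genes — arranged in
clusters with intergenic spacers of 1 to ~30 nt, all on one DNA strand —
plus an enzyme (TilS, tRNA isoleucine lysidine synthase) that recodes
tRNA-Met(CAU) to read the isoleucine codon AUA. This package implements the
complete desk analysis of that system: annotation parsing, tRNA inventory
semantics, cluster detection, the codon-usage ratio statistic, favorability
classification, and cross-clade comparison, validated throughout against a
ground-truthed synthetic genome generator.

## The model, step by step

### Codon recognition

Anticodons are stored 5′→3′; the cognate codon is the reverse complement
(`anticodon_to_codon("CAU")` is `"AUG"`). Diagram conventions that write
anticodons 3′→5′ are converted at the I/O boundary, never inside the model.
Wobble is modeled only at the codon third position / anticodon position 34,
as a configurable map from the position-34 base to the codon third-position
bases it can read. The default is conservative: G34 reads C and U (so one
tRNA-Tyr(GUA) covers UAC and UAU), while A, C and U pair Watson-Crick only.
The Watson-Crick partner is always a member of the recognition set, so
wobble sets are supersets of strict sets by construction. TilS is modeled
as a recognition-set rewrite — identity Met/AUG with anticodon CAU becomes
Ile/AUA with recognition exactly {AUA} — not as a chemistry simulation;
nothing downstream needs more than the changed recognition set.

### The ratio statistic

Codon frequencies are percentages over the 61 sense codons with stop codons
excluded; this is the only reading under which the published 61-row
comparison is self-consistent (a terminal stop is removed from each CDS;
internal stops and ambiguous codons are excluded from the denominator and
reported on a QC side channel). The statistic is mean-then-divide:

$$R_c = \frac{\tfrac{1}{V}\sum_v f_{v,c}}{f_{\mathrm{host},c}},$$

matching the published footnote ("average codon usage of the two viruses
divided by codon usage of the host"); with one virus it degrades to a plain
ratio. A host frequency of zero makes $R_c$ undefined (`NA`, flagged),
never infinite. Presentation rounding is half-up to two decimals
(`round_half_up()`), matching the printed table; internal comparisons use
unrounded values.

### Favorability

A virus tRNA "assists" when it reads a codon with $R_c > \tau$; the default
$\tau = 1$ exactly, with $R_c = \tau$ labeled `boundary`, not assisting.
The default counting unit is the distinct recognized codon, not the gene:
that is the reading under which the reference virus's 11 tRNA genes (8
distinct codons) yield 7 assisting codons, the published "only 7 help"
count. A per-gene mode exists for sensitivity analysis (three Asn-AAC
copies then count three times). Pseudogenes and identity-unknown tRNAs are
excluded from classification with a warning but remain in gene totals,
mirroring how the published per-virus totals include pseudogenes.

### Cluster detection

Clustering is greedy left-to-right chaining over the genome-ordered tRNA
inventory. A junction extends the chain when (i) the spacer
(`start(next) − end(prev) − 1`; the published tables never define the
convention, but this one reproduces their "nt between two adjacent tRNAs"
columns) is at most `max_gap_nt`, (ii) the strand matches, and (iii) the
intervening non-tRNA features are admissible — none in strict mode (the
survey definition: "no intervening genes; 2 or more"), at most 3 in relaxed
mode. The relaxed defaults (`max_gap_nt = 2000`, ≤3 intervening) were
chosen so that every published interrupted cluster row (gaps of 985, 1041,
1142, 1416 nt containing a CDS) remains one cluster while the ~30 kb orphan
tRNA-Thr of the SAG-clade genomes can never join; both are configuration,
not hard-coded. Overlapping tRNA annotations are an error (annotation
conflict), never silently merged. Genome position is classified by cluster
midpoint against thirds of the genome length, closed on the left (a
midpoint exactly at L/3 is "first"); the published "near the center" /
"first third" language is qualitative, so the midpoint rule is this
package's own convention. `cotranscription_candidate()` is a deliberately
simple screen — one strand, every spacer ≤ 500 nt, no interruptions — for
clusters compatible with transcription as a single precursor.

### Comparative bookkeeping

Identity granularity is (amino acid, cognate codon) — the column semantics
of the per-clade tables; anticodon-level granularity is not needed because
the tables never distinguish synonymous anticodons. One subtlety is
inherited from the published bookkeeping: common/shared sets are counted at
identity level, but unique-per-clade counts are at *gene column* level — the
Pbi clade carries two distinct Thr-ACG gene columns and the published count
treats them as two unique genes (2/3/4 for NC64A/Pbi/SAG). The
presence matrix therefore carries a per-clade column-multiplicity attribute
(derived from the fixtures' copy index, defaulting to 1), and
`clade_shared_unique()` reports both the identity sets and the gene-column
counts. Pseudogenes count toward presence by default, configurable.
Gene-order similarity is normalized LCS, $2\,\mathrm{LCS}(a,b)/(|a|+|b|)$ —
the source offers no metric for its within-clade synteny observation, so
this artifact choice is validated only against a brute-force LCS oracle.

## The synthetic data generator

The generator emulates the statistical structure the analysis consumes, and
only that:

* CDS codons drawn i.i.d. from a configured 61-codon table (e.g. the
  published virus or host columns), so corpora recover their generating
  table within binomial error; there is deliberately no codon
  autocorrelation, codon-pair bias or GC gradient, because the analysis
  uses only marginal codon frequencies.
* Intergenic sequence GC-matched to the coding composition, so whole-genome
  GC reflects the configured table (~41% for the virus column, ~68% for the
  host column).
* tRNA genes on a fixed 72 nt exonic scaffold: anticodon at positions
  34-36, concrete instances of the Box A/B Pol III promoter consensus
  embedded at offsets 8 and 49 (the source cites but does not print the
  consensus, so the defaults — `TRGCNNARYNN`, `GGTTCGANNCC`, 2 mismatches —
  are literature-canonical configuration), no terminal CCA, optional intron
  inserted 1 nt 3′ of the anticodon, pseudogenes realized as an annotation
  flag plus a D-arm disruption. This is scaffold realism sufficient for
  parser, geometry and motif-scan tests; it is *not* a foldable tRNA, and
  passing tests say nothing about cloverleaf structure, which is out of
  scope.
* Clusters laid out from an explicit spec (identities, spacers, strand,
  interrupting CDSs, orphan distances), with the truth record carrying
  every coordinate, spacer and flag; all randomness flows from one seed and
  identical configs re-generate byte-identical files.

Because real annotation is messier than this (fragmented drafts,
inconsistent qualifiers, overlapping genes), round-trip success on
generated genomes demonstrates internal consistency of the model and
detectors, not robustness to arbitrary third-party records.

## Packaged fixtures and known data conflicts

The published tables ship as TSV transcriptions with an MD5 manifest
(fixtures are data; tampering is an error, not a silent re-read). The wide
color-coded cluster tables do not survive text extraction losslessly: cell
colors (the pseudogene markings) are unrecoverable, and several rows print
more spacer values than their printed totals allow. The transcription
therefore reconstructs per-virus column occupancy from the printed totals,
spacer counts, footnotes and prose constraints, and every judgment call is
listed in the `fixture_errata` fixture. Known conflicts internal to the
printed source are preserved and surfaced rather than repaired: four
printed ratios (GAU, GGG, CUU, AUG) disagree with the footnote formula
applied to the printed frequencies (the pipeline reproduces 57/61 within
±0.015 and reports the four formula values); the prose totals 410 genes and
17 identities disagree with the summed printed totals (407) and the heading
union (18); `summary_stats()` reports the computed values and flags the
stated ones as discrepancies.

## Numerical and degenerate-input choices

Computed frequency tables must sum to 100 within 1e-9; printed-fixture
columns are only required to land in [95, 100.5] because the printed
columns themselves sum to 99.42/95.57/99.64. Ratio comparisons against
printed values use ±0.015 (half a unit in the last printed place, plus
rounding slack). Empty feature lists, empty inventories, single-clade
matrices, zero-length marker lists and all-ambiguous sequences are handled
explicitly (empty results or informative errors, as contracts state).
Sequence identity keys guard against R's `paste0` zero-length recycling.
Genomes are single-contig; draft multi-contig assemblies would be processed
per contig by the caller.

## Problem sizes

The test suite validates cluster recovery on 100 seeded genomes of 8-36 kb
(36 kb when an orphan is placed ~25-31 kb downstream), statistical recovery
on corpora of ~20-25 thousand codons, and the fixture-driven analyses on
the full 41-genome cohort; these sizes give tight binomial checks (3σ per
codon) while keeping the whole suite around a minute on one core. The
acceptance script re-simulates the 100-genome recovery sweep and two 60 kb
GC-calibration genomes per run.

## Limitations

* The favorability classification inherits the fixture reconstruction of
  each virus's tRNA complement; colors lost in transcription mean
  pseudogene status in the real tables is not represented.
* Wobble rules are third-position only; modified-base pairing beyond TilS
  (e.g. inosine at position 34) is not modeled.
* Cluster detection assumes correct, non-overlapping tRNA annotation;
  it does not re-predict tRNAs from sequence (structure prediction is out
  of scope).
* The synteny score treats gene order as a flat label sequence; it ignores
  spacer lengths, strand and duplications beyond label multiplicity.
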