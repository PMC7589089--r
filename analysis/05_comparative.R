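#!/usr/bin/env Rscript
# Step 5 — cross-clade comparison over the 41-genome cohort.
#
# Presence/absence of tRNA identities across the three clades, shared and
# unique sets, per-identity incidence, cohort totals (with the known
# stated-vs-computed conflicts surfaced), within- vs between-clade gene
# order similarity, and marker concatenation on the simulated cohort
# (tRNA-Gly + tRNA-Tyr + tRNA-Arg, the phylogenetic marker set).

suppressPackageStartupMessages(library(chlorotrna))

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- load_cluster_fixtures()
pm <- presence_matrix(cohort)
write.table(data.frame(identity = rownames(pm), pm, check.names = FALSE),
            file.path(out, "presence_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

su <- clade_shared_unique(pm)
cat(sprintf("identities in all three clades (%d): %s\n",
            length(su$common_all_clades),
            paste(su$common_all_clades, collapse = ", ")))
for (cl in names(su$unique_per_clade)) {
  cat(sprintf("unique to %s: %s (as gene columns: %d)\n", cl,
              paste(su$unique_per_clade[[cl]], collapse = ", "),
              su$unique_gene_counts[[cl]]))
}
jsonlite::write_json(
  list(common_all_clades = su$common_all_clades,
       unique_per_clade = su$unique_per_clade,
       unique_gene_counts = as.list(su$unique_gene_counts),
       shared_pairs = su$shared_pairs),
  file.path(out, "clade_shared_unique.json"), auto_unbox = FALSE, digits = NA)

ss <- summary_stats(cohort, expected = list(total_genes = 410,
                                            distinct_identities = 17))
cat(sprintf("cohort: %d genomes, %d tRNA genes, %d identities, %d amino acids\n",
            ss$n_genomes, ss$total_genes, ss$distinct_identities,
            ss$distinct_amino_acids))
if (nrow(ss$discrepancies)) {
  cat("stated-vs-computed conflicts (reported, not resolved):\n")
  print(as.data.frame(ss$discrepancies), row.names = FALSE)
}
write.table(ss$identity_incidence, file.path(out, "identity_incidence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# gene-order similarity: within-clade synteny vs between-clade divergence
viruses <- unique(cohort$virus)
orders <- lapply(split(cohort, cohort$virus), function(d) {
  d$codon[order(d$position)]
})
clade_of <- vapply(split(cohort$clade, cohort$virus), `[`, character(1), 1)
sim <- matrix(NA_real_, length(viruses), length(viruses),
              dimnames = list(viruses, viruses))
for (a in viruses) {
  for (b in viruses) {
    sim[a, b] <- gene_order_similarity(orders[[a]], orders[[b]])
  }
}
write.table(data.frame(virus = rownames(sim), round(sim, 3),
                       check.names = FALSE),
            file.path(out, "gene_order_similarity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
within <- sim[outer(clade_of[viruses], clade_of[viruses], "==") &
                upper.tri(sim)]
between <- sim[outer(clade_of[viruses], clade_of[viruses], "!=") &
                 upper.tri(sim)]
cat(sprintf("gene-order similarity: within-clade mean %.2f, between-clade mean %.2f\n",
            mean(within), mean(between)))

# marker concatenation on the simulated cohort (needs 01_simulate.R output)
sim_dir <- "scratch/sim"
if (dir.exists(sim_dir)) {
  gbks <- list.files(sim_dir, pattern = "\\.gbk$", full.names = TRUE)
  records <- lapply(gbks, read_genbank)
  fasta <- file.path(out, "concatenated_markers.fasta")
  seqs <- withCallingHandlers(
    concatenate_markers(records, c("GGA", "UAC", "AGA"), file = fasta),
    warning = function(w) {
      cat("  note:", conditionMessage(w), "\n")
      invokeRestart("muffleWarning")
    })
  cat(sprintf("concatenated Gly+Tyr+Arg markers for %d/%d simulated genomes -> %s\n",
              length(seqs), length(records), fasta))
} else {
  cat("scratch/sim not found; run analysis/01_simulate.R for marker export\n")
}
cat("comparative tables written to", out, "\n")
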