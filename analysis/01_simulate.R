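#!/usr/bin/env Rscript
# Step 1 — simulate a ground-truth cohort.
#
# Builds one GC-rich host genome and three viruses mirroring the cluster
# architecture of the three chlorovirus clades: an NC64A-style 14-gene
# cluster with 1-30 nt spacers, a SAG-style cluster in the first genome
# third with a tRNA-Thr orphan 30 kb downstream, and a Pbi-style interrupted
# cluster (a CDS inside a 1416 nt gap). Coding composition is drawn from the
# published codon-usage columns, so the host is ~67-68% GC and the viruses
# ~41% GC. Genome files (GenBank, GFF3, FASTA, truth JSON) go to
# scratch/sim/; a summary table goes to results/.

suppressPackageStartupMessages(library(chlorotrna))

out_files <- "scratch/sim"
out_tables <- "results"
dir.create(out_files, recursive = TRUE, showWarnings = FALSE)
dir.create(out_tables, recursive = TRUE, showWarnings = FALSE)

cu <- load_codon_usage_fixture()
virus_tab <- setNames(cu$pbcv1$freq, cu$pbcv1$codon)
host_tab <- setNames(cu$host$freq, cu$host$codon)
norm <- function(x) x / sum(x) * 100

entries <- function(codons, tyr_intron = 13L) {
  tibble::tibble(
    amino_acid = codon_to_aa(codons, three_letter = TRUE),
    anticodon = rna(reverse_complement(dna(codons))),
    pseudogene = FALSE,
    intron_offset = ifelse(codons == "UAC", 1L, NA_integer_),
    intron_length = ifelse(codons == "UAC", tyr_intron, NA_integer_))
}

specs <- list(
  simNC64A = list(
    clade = "NC64A", seed = 101, length = 60000,
    spec = cluster_spec(
      entries(c("UUG", "AUA", "AAC", "UUA", "AGA", "AAC", "GGA", "AAC",
                "AAG", "CAG", "AAG", "UAC", "AAA", "AAG")),
      spacers = c(25, 23, 24, 3, 23, 3, 27, 3, 22, 23, 23, 30, 1))),
  simSAG = list(
    clade = "SAG", seed = 102, length = 60000,
    spec = cluster_spec(
      entries(c("AGU", "AGA", "AAC", "GGA", "AUU", "AAC", "AUG", "GAC",
                "GUU", "UAC", "AAG", "AAC"), tyr_intron = 10L),
      spacers = c(4, 25, 22, 22, 25, 23, 22, 22, 2, 21, 4),
      cluster_start = 5000,
      orphans = tibble::tibble(amino_acid = "Thr", anticodon = "AGU",
                               distance = 30000))),
  simPbi = list(
    clade = "Pbi", seed = 103, length = 60000,
    spec = cluster_spec(
      entries(c("AUA", "UUA", "UUC", "AGA", "GGA", "AAC", "AAC", "UAC",
                "AAG", "ACG")),
      spacers = c(24, 24, 23, 3, 23, 22, 22, 2, 1416),
      interruptions = tibble::tibble(junction = 9, cds_length = 1200))))

rows <- list()
for (id in names(specs)) {
  s <- specs[[id]]
  cfg <- genome_sim_config(seed = s$seed, genome_length = s$length,
                           cds_count = 40, cds_codons = 300,
                           codon_table = norm(virus_tab),
                           cluster = s$spec, clade = s$clade, id = id)
  gen <- generate_virus_genome(cfg)
  write_genome_files(gen, out_files)
  rows[[id]] <- tibble::tibble(
    genome = id, clade = s$clade, role = "virus",
    length = gen$record$length, gc = round(gc_content(gen$record), 2),
    trna_genes = nrow(gen$truth$genes),
    orphans = nrow(gen$truth$orphan))
  cat(sprintf("%s: %d tRNA genes, GC %.1f%%\n", id,
              nrow(gen$truth$genes), gc_content(gen$record)))
}

host_cfg <- genome_sim_config(seed = 104, genome_length = 80000,
                              cds_count = 70, cds_codons = 330,
                              codon_table = norm(host_tab),
                              clade = "host", id = "simHost")
host <- generate_host_genome(host_cfg)
write_genome_files(host, out_files)
rows[["simHost"]] <- tibble::tibble(
  genome = "simHost", clade = "host", role = "host",
  length = host$record$length, gc = round(gc_content(host$record), 2),
  trna_genes = 0L, orphans = 0L)
cat(sprintf("simHost: GC %.1f%% (GC-rich host)\n", gc_content(host$record)))

summary <- dplyr::bind_rows(rows)
write.table(summary, file.path(out_tables, "simulated_genomes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out_tables, "simulated_genomes.tsv"), "\n")
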