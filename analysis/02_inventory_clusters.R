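#!/usr/bin/env Rscript
# Step 2 — tRNA inventories and cluster detection.
#
# Reads the simulated genomes (GenBank) emitted by 01_simulate.R, rebuilds
# their tRNA inventories from annotation alone, detects clusters under the
# relaxed rules, verifies the result against the generator's truth JSON, and
# writes the per-genome inventory and a cluster report. Run 01 first.

suppressPackageStartupMessages(library(chlorotrna))

sim_dir <- "scratch/sim"
out <- "results"
stopifnot(dir.exists(sim_dir))

gbks <- list.files(sim_dir, pattern = "\\.gbk$", full.names = TRUE)
records <- lapply(gbks, read_genbank)
names(records) <- vapply(records, `[[`, character(1), "id")

inventories <- lapply(records, build_inventory)
long <- dplyr::bind_rows(inventories)
export_inventory_tsv(long, file.path(out, "simulated_inventory.tsv"))

report <- cluster_table(records)
write.table(report, file.path(out, "cluster_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report[, c("genome", "clade", "total_trnas", "n_clusters", "n_orphans")])

# verification against the generator truth: counts, spacers, orphans
for (id in names(records)) {
  truth <- jsonlite::read_json(file.path(sim_dir, paste0(id, ".truth.json")),
                               simplifyVector = TRUE)
  det <- detect_clusters(inventories[[id]], records[[id]]$features,
                         cluster_params(), records[[id]]$length)
  n_truth <- if (is.data.frame(truth$genes)) nrow(truth$genes) else 0L
  stopifnot(nrow(inventories[[id]]) == n_truth)
  if (length(det$clusters)) {
    stopifnot(identical(as.integer(det$clusters[[1]]$spacers),
                        as.integer(truth$spacers)))
    cat(sprintf("%s: cluster of %d genes in the %s third%s\n", id,
                det$clusters[[1]]$n_genes, det$clusters[[1]]$genome_third,
                if (nrow(det$orphans)) {
                  sprintf(", orphan %s at %d nt", det$orphans$amino_acid,
                          det$orphans$distance_nt)
                } else {
                  ""
                }))
    cat(sprintf("%s: co-transcription candidate: %s\n", id,
                cotranscription_candidate(det$clusters[[1]])))
  } else {
    cat(sprintf("%s: no tRNA cluster (host)\n", id))
  }
}
cat("inventory and cluster report written to", out, "\n")
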