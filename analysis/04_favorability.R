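#!/usr/bin/env Rscript
# Step 4 — which virus tRNAs help overcome the host's codon usage bias.
#
# Classifies each virus's recognized-codon set against the virus/host ratio
# table (threshold 1, distinct-codon counting), reports the assisting vs
# neutral split, the TilS benefit (the recoded tRNA-Met reading AUA), and a
# wobble sensitivity check.

suppressPackageStartupMessages(library(chlorotrna))

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cu <- load_codon_usage_fixture()
rat <- cub_ratio(list(cu$pbcv1, cu$an69c), cu$host)
rec <- fixture_recognized_codons()

inv_of <- function(codons) {
  tibble::tibble(
    amino_acid = codon_to_aa(codons, three_letter = TRUE), codon = codons,
    anticodon = rna(reverse_complement(dna(codons))),
    pseudogene = FALSE, identity_known = TRUE)
}

rows <- list()
for (virus in c("pbcv1", "an69c")) {
  label <- toupper(sub("pbcv1", "PBCV-1", virus))
  fav <- classify_favorability(inv_of(rec[[virus]]), rat)
  cat(sprintf("%s: %d distinct recognized codons, %d assisting\n",
              label, fav$n_distinct_codons, fav$n_assisting))
  d <- fav$codons
  d$virus <- label
  rows[[virus]] <- d
  # wobble sensitivity: recognition expanded at anticodon position 34
  wob <- classify_favorability(inv_of(rec[[virus]]), rat,
                               favorability_params(use_wobble = TRUE))
  cat(sprintf("  with wobble: %d codons recognized, %d assisting\n",
              wob$n_distinct_codons, wob$n_assisting))
}
fav_tab <- dplyr::bind_rows(rows)
write.table(fav_tab, file.path(out, "favorability.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tb <- tils_benefit(rat)
cat(sprintf("TilS benefit: recoded tRNA-Met reads %s, ratio %.2f (%s)\n",
            tb$codon, round_half_up(tb$ratio), tb$label))
jsonlite::write_json(
  list(pbcv1 = list(distinct = sum(fav_tab$virus == "PBCV-1"),
                    assisting = sum(fav_tab$virus == "PBCV-1" &
                                      fav_tab$label == "assisting")),
       an69c = list(distinct = sum(fav_tab$virus == "AN69C"),
                    assisting = sum(fav_tab$virus == "AN69C" &
                                      fav_tab$label == "assisting")),
       tils = list(codon = tb$codon, ratio = round_half_up(tb$ratio),
                   label = tb$label)),
  file.path(out, "favorability.json"), auto_unbox = TRUE, digits = NA)
cat("favorability tables written to", out, "\n")
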