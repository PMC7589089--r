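# GFF3 + FASTA reader (rtracklayer / Biostrings) and a deterministic GFF3
# writer. Parent/child structures (gene -> tRNA -> exon) collapse to one
# feature carrying exon sub-intervals, mirroring the GenBank join() model.

#' Read an annotated genome from GFF3 + FASTA
#'
#' Same contract as [read_genbank()]: returns a [genome_record()] whose tRNA
#' and CDS features carry exon sub-intervals, product/anticodon qualifiers and
#' pseudogene flags. `gene` wrappers are collapsed onto their child feature;
#' `exon` children become the parent's exon sub-intervals.
#'
#' @param gff_path Path to a GFF3 file (version pragma required).
#' @param fasta_path Path to a FASTA file whose first record id matches the
#'   GFF3 seqid.
#' @param clade Optional clade label (default from a `clade=` attribute on any
#'   `region` line, else `"other"`).
#' @return A [genome_record()].
#' @export
read_gff3_fasta <- function(gff_path, fasta_path, clade = NULL) {
  first <- readLines(gff_path, n = 1, warn = FALSE)
  if (!grepl("^##gff-version\\s+3", first)) {
    stop("missing ##gff-version 3 pragma in ", gff_path)
  }
  fa <- Biostrings::readDNAStringSet(fasta_path)
  fa_id <- sub("\\s.*$", "", names(fa)[1])
  sequence <- as.character(fa[[1]])

  gr <- rtracklayer::import(gff_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr) && !all(seqids == fa_id)) {
    stop("GFF3 seqid does not match FASTA record id '", fa_id, "'")
  }
  if (length(gr) && max(GenomicRanges::end(gr)) > nchar(sequence)) {
    stop("GFF3 coordinate beyond sequence end")
  }

  types <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(gr))
  }

  region_clade <- NA_character_
  if (any(types == "region") && "clade" %in% names(md)) {
    region_clade <- as.character(md$clade[types == "region"][1])
  }

  keep <- !(types %in% c("region", "gene", "exon", "intron"))
  rows <- list()
  for (i in which(keep)) {
    kind <- if (types[i] %in% c("tRNA", "CDS")) types[i] else "other"
    kids <- which(types == "exon" & !is.na(parents) & parents == ids[i])
    exons <- NULL
    if (length(kids) > 1) {
      exons <- data.frame(start = GenomicRanges::start(gr)[kids],
                          end = GenomicRanges::end(gr)[kids])
      exons <- exons[order(exons$start), , drop = FALSE]
      rownames(exons) <- NULL
    }
    product <- if ("product" %in% names(md)) as.character(md$product[i]) else NA
    anticodon <- if ("anticodon" %in% names(md)) {
      ac <- as.character(md$anticodon[i])
      if (!is.na(ac)) toupper(dna(ac)) else NA_character_
    } else {
      NA_character_
    }
    pseudo <- "pseudo" %in% names(md) &&
      isTRUE(tolower(as.character(md$pseudo[i])) %in% c("true", "1"))
    rows[[length(rows) + 1]] <- tibble(
      feature_id = ids[i] %||% sprintf("feat%03d", i), kind = kind,
      start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i],
      strand = ifelse(as.character(BiocGenerics::strand(gr))[i] == "-", "-", "+"),
      product = product %||% NA_character_, anticodon = anticodon,
      pseudo = pseudo, exons = list(exons))
  }
  ft <- if (length(rows)) bind_rows(rows) else feature_table()
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  genome_record(fa_id, sequence, ft,
                clade = clade %||%
                  (if (is.na(region_clade)) "other" else region_clade))
}

#' Write a genome record as GFF3 (+ optional FASTA)
#'
#' Emits a `##gff-version 3` pragma, a `region` line carrying the clade, one
#' line per feature and `exon` children for multi-exon features, with a fixed
#' attribute order so output is deterministic.
#'
#' @param record A [genome_record()].
#' @param gff_path Output GFF3 path.
#' @param fasta_path Optional output FASTA path for the sequence.
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(record, gff_path, fasta_path = NULL) {
  validate_genome_record(record)
  con <- file(gff_path, "wb")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")
  w("##gff-version 3")
  w("##sequence-region %s 1 %d", record$id, record$length)
  w(paste(record$id, "chlorotrna", "region", 1, record$length, ".", "+", ".",
          sprintf("ID=%s;clade=%s", record$id, record$clade), sep = "\t"))
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    attrs <- sprintf("ID=%s", ft$feature_id[i])
    if (!is.na(ft$product[i])) {
      attrs <- paste0(attrs, ";product=", ft$product[i])
    }
    if (!is.na(ft$anticodon[i])) {
      attrs <- paste0(attrs, ";anticodon=", tolower(ft$anticodon[i]))
    }
    if (isTRUE(ft$pseudo[i])) attrs <- paste0(attrs, ";pseudo=true")
    type <- if (ft$kind[i] %in% c("tRNA", "CDS")) ft$kind[i] else "misc_feature"
    w(paste(record$id, "chlorotrna", type, ft$start[i], ft$end[i], ".",
            ft$strand[i], ".", attrs, sep = "\t"))
    ex <- ft$exons[[i]]
    if (!is.null(ex)) {
      for (j in seq_len(nrow(ex))) {
        w(paste(record$id, "chlorotrna", "exon", ex$start[j], ex$end[j], ".",
                ft$strand[i], ".",
                sprintf("ID=%s.exon%d;Parent=%s", ft$feature_id[i], j,
                        ft$feature_id[i]), sep = "\t"))
      }
    }
  }
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(setNames(record$sequence, record$id))
    Biostrings::writeXStringSet(ss, fasta_path, width = 70)
  }
  invisible(gff_path)
}
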