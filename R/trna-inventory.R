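# From annotated tRNA features to a semantically rich inventory: identities,
# codon recognition (wobble, TilS), intron geometry, CCA status.
#
# Anticodons are stored 5'->3' (the figure convention 3'->5' is converted at
# the I/O boundary, never in the model). Codons/anticodons are rendered RNA
# in all reports to match the published tables.

#' Cognate codon of an anticodon
#'
#' The anticodon, written 5'->3', pairs antiparallel with its codon, so the
#' cognate codon is the reverse complement: anticodon CAU (3'-UAC-5') reads
#' AUG, anticodon GUA reads UAC.
#'
#' @param anticodon RNA triplet(s) over `{A,C,G,U}`, written 5'->3'.
#' @return RNA triplet(s): the cognate codon(s).
#' @export
anticodon_to_codon <- function(anticodon) {
  bad <- !grepl("^[ACGU]{3}$", toupper(anticodon))
  if (any(bad)) {
    stop("anticodon must be an RNA triplet over {A,C,G,U}: ",
         paste(anticodon[bad], collapse = ", "))
  }
  rna(reverse_complement(toupper(dna(anticodon))))
}

#' Wobble pairing rules for anticodon position 34
#'
#' Position 34 (the 5' base of the anticodon) pairs with the codon third
#' position. By default G34 wobbles to read both C and U, so a single
#' tRNA-Tyr(GUA) recognizes UAC and UAU; A, C and U pair Watson-Crick only.
#' The Watson-Crick partner is always included.
#'
#' @param enabled Apply wobble expansions at all? When `FALSE`,
#'   recognition sets are strict singletons.
#' @param pairings Named list: anticodon position-34 base -> character vector
#'   of codon third-position bases it can read.
#' @return A `wobble_rules` list.
#' @export
wobble_rules <- function(enabled = TRUE,
                         pairings = list(G = c("C", "U"), A = "U",
                                         C = "G", U = "A")) {
  wc <- c(G = "C", A = "U", C = "G", U = "A")
  for (b in names(pairings)) {
    if (!(wc[[b]] %in% pairings[[b]])) {
      stop("pairings for ", b, " must include the Watson-Crick partner ",
           wc[[b]])
    }
  }
  structure(list(enabled = enabled, pairings = pairings),
            class = "wobble_rules")
}

#' Codons recognized by an anticodon under wobble rules
#'
#' @param anticodon RNA triplet, 5'->3'.
#' @param rules A [wobble_rules()] object.
#' @return Sorted character vector of RNA codons; always contains the strict
#'   Watson-Crick codon.
#' @export
wobble_recognition_set <- function(anticodon, rules = wobble_rules()) {
  strict <- anticodon_to_codon(anticodon)
  if (!rules$enabled) return(strict)
  base34 <- substr(toupper(anticodon), 1, 1)
  thirds <- rules$pairings[[base34]]
  if (is.null(thirds)) thirds <- substr(strict, 3, 3)
  sort(unique(paste0(substr(strict, 1, 2), thirds)))
}

#' Apply the TilS recoding to a tRNA-Met gene
#'
#' tRNA isoleucine lysidine synthase converts C34 of the tRNA-Met(CAU)
#' anticodon to lysidine; the modified base pairs with A, so the tRNA stops
#' reading AUG and instead reads the isoleucine codon AUA. Modeled as a
#' recognition-set rewrite: the returned copy has identity Ile/AUA and
#' recognition set exactly `{"AUA"}`; the input is unmodified.
#'
#' @param trna A one-row inventory tibble (see [build_inventory()]) with
#'   identity Met/AUG and anticodon CAU.
#' @return The recoded one-row tibble, with `tils_recoded = TRUE`.
#' @export
apply_tils <- function(trna) {
  stopifnot(is.data.frame(trna), nrow(trna) == 1)
  if (!identical(trna$amino_acid, "Met") || !identical(trna$codon, "AUG") ||
      !identical(trna$anticodon, "CAU")) {
    stop("TilS modifies the CAU anticodon of tRNA-Met only (got ",
         trna$amino_acid, "/", trna$codon, ", anticodon ", trna$anticodon, ")")
  }
  out <- trna
  out$amino_acid <- "Ile"
  out$codon <- "AUA"
  out$recognition <- list("AUA")
  out$tils_recoded <- TRUE
  out
}

#' Intron geometry of a tRNA gene
#'
#' Chlorovirus tRNA-Tyr introns sit one exonic nucleotide 3' of the
#' anticodon. Returns the number of exonic nucleotides between the anticodon
#' 3' end and the intron start, together with the intron length, or `NULL`
#' for single-exon genes.
#'
#' @param trna One inventory row (one-row tibble or list) with `sequence`
#'   (spliced, coding strand), `anticodon`, `strand` and `exons`.
#' @return `list(offset, length)` or `NULL`.
#' @export
intron_geometry <- function(trna) {
  if (is.data.frame(trna)) {
    stopifnot(nrow(trna) == 1)
    trna <- as.list(trna)
    trna$exons <- trna$exons[[1]]
  }
  ex <- trna$exons
  if (is.null(ex) || nrow(ex) < 2) return(NULL)
  if (nrow(ex) > 2) stop("more than one intron is not supported")
  anticodon_dna <- toupper(dna(trna$anticodon))
  spliced <- toupper(trna$sequence)
  hits <- gregexpr(anticodon_dna, spliced, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    stop("anticodon ", trna$anticodon, " not locatable in exonic sequence")
  }
  ac_start <- hits[which.min(abs(hits - 34L))]
  ac_end <- ac_start + 2L
  widths <- ex$end - ex$start + 1L
  if (identical(trna$strand, "-")) widths <- rev(widths)
  exon1_len <- widths[1]          # exonic nt 5' of the intron
  intron_len <- if (identical(trna$strand, "-")) {
    ex$start[2] - ex$end[1] - 1L
  } else {
    ex$start[2] - ex$end[1] - 1L
  }
  list(offset = as.integer(exon1_len - ac_end), length = as.integer(intron_len))
}

#' Does a tRNA gene encode the 3' CCA end?
#'
#' Chlorovirus tRNA genes lack the 3'-terminal CCA needed for
#' aminoacylation (it is added post-transcriptionally). True iff the spliced
#' gene sequence, read 5'->3' on the coding strand, ends in CCA.
#'
#' @param trna One inventory row, or a character sequence.
#' @return Logical flag.
#' @export
detect_cca_end <- function(trna) {
  s <- if (is.character(trna)) trna else {
    if (is.data.frame(trna)) trna$sequence[[1]] else trna$sequence
  }
  if (!nzchar(s %||% "")) stop("sequence required for CCA detection")
  grepl("CCA$", toupper(dna(s)))
}

# Identity from qualifiers: anticodon preferred, else product string
# ("tRNA-Tyr (GTA)" or "tRNA-Tyr"). Returns list(aa3, codon_rna, anticodon_rna).
resolve_trna_identity <- function(product, anticodon_dna) {
  anticodon <- NA_character_
  if (!is.na(anticodon_dna) && grepl("^[ACGT]{3}$", anticodon_dna)) {
    anticodon <- rna(anticodon_dna)
  } else if (!is.na(product)) {
    m <- regmatches(product, regexec("\\(([ACGTUacgtu]{3})\\)", product))[[1]]
    if (length(m) == 2) anticodon <- rna(toupper(m[2]))
  }
  if (!is.na(anticodon)) {
    codon <- anticodon_to_codon(anticodon)
    return(list(aa = codon_to_aa(codon, three_letter = TRUE), codon = codon,
                anticodon = anticodon))
  }
  aa <- NA_character_
  if (!is.na(product)) {
    m <- regmatches(product, regexec("tRNA-([A-Za-z]{3})", product))[[1]]
    if (length(m) == 2 && m[2] %in% Biostrings::AMINO_ACID_CODE) aa <- m[2]
  }
  list(aa = aa, codon = NA_character_, anticodon = NA_character_)
}

#' Build the tRNA inventory of a genome
#'
#' One row per tRNA feature, in genome order. Identities are resolved from
#' the anticodon qualifier (preferred) or the product string; features with
#' neither are kept as identity-unknown with a warning. Pseudogenes are
#' flagged, never dropped.
#'
#' @param record A [genome_record()].
#' @return A tibble with columns `genome`, `clade`, `index`, `amino_acid`
#'   (3-letter), `codon`, `anticodon` (both RNA, 5'->3'), `start`, `end`,
#'   `strand`, `spacer_to_next`, `pseudogene`, `intron_offset`,
#'   `intron_length`, `cca`, `identity_known`, `sequence`, `exons`.
#' @export
build_inventory <- function(record) {
  tr <- extract_features(record, "tRNA")
  n <- nrow(tr)
  if (n == 0) return(empty_inventory())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- tr[i, ]
    ident <- resolve_trna_identity(f$product, f$anticodon)
    if (is.na(ident$codon)) {
      warning("tRNA feature ", f$feature_id,
              " has no parsable anticodon or product codon; ",
              "recorded as identity-unknown")
    }
    seq <- feature_sequence(record, f)
    geom <- if (!is.na(ident$anticodon)) {
      g <- tryCatch(
        intron_geometry(list(sequence = seq, anticodon = ident$anticodon,
                             strand = f$strand, exons = f$exons[[1]])),
        error = function(e) NULL)
      g
    } else {
      NULL
    }
    rows[[i]] <- tibble(
      genome = record$id, clade = record$clade, index = i,
      feature_id = f$feature_id,
      amino_acid = ident$aa, codon = ident$codon, anticodon = ident$anticodon,
      start = f$start, end = f$end, strand = f$strand,
      spacer_to_next = NA_integer_,
      pseudogene = isTRUE(f$pseudo),
      intron_offset = if (is.null(geom)) NA_integer_ else geom$offset,
      intron_length = if (is.null(geom)) NA_integer_ else geom$length,
      cca = detect_cca_end(seq),
      identity_known = !is.na(ident$codon),
      tils_recoded = FALSE,
      sequence = seq, exons = f$exons)
  }
  inv <- bind_rows(rows)
  if (n > 1) {
    inv$spacer_to_next[-n] <- inv$start[-1] - inv$end[-n] - 1L
  }
  inv
}

empty_inventory <- function() {
  tibble(genome = character(), clade = character(), index = integer(),
         feature_id = character(), amino_acid = character(),
         codon = character(), anticodon = character(), start = integer(),
         end = integer(), strand = character(), spacer_to_next = integer(),
         pseudogene = logical(), intron_offset = integer(),
         intron_length = integer(), cca = logical(),
         identity_known = logical(), tils_recoded = logical(),
         sequence = character(), exons = list())
}

#' Export an inventory as TSV
#'
#' Writes the tabular columns (sequence and exon list columns dropped) as a
#' tab-separated file.
#'
#' @param inventory Tibble from [build_inventory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_inventory_tsv <- function(inventory, path) {
  cols <- c("genome", "index", "amino_acid", "codon", "anticodon", "start",
            "end", "strand", "spacer_to_next", "pseudogene", "intron_offset",
            "intron_length", "cca")
  write.table(inventory[, intersect(cols, names(inventory))], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
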