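# RNA polymerase III type-2 (class II) intragenic promoter scan. Type-2
# promoters are two 11-mer intragenic elements, Box A and Box B, recognized
# by TFIIIC. The published analysis cites but does not print the consensus
# sequences, so the defaults here are the literature-canonical 11-mers and
# are configuration, not a claim of the source data.

#' Box A/B promoter motif configuration
#'
#' @param box_a_consensus,box_b_consensus IUPAC consensus strings, 11 nt.
#' @param max_mismatches Mismatch budget per window.
#' @return A `box_motif_config` list.
#' @export
box_motif_config <- function(box_a_consensus = "TRGCNNARYNN",
                             box_b_consensus = "GGTTCGANNCC",
                             max_mismatches = 2) {
  if (nchar(box_a_consensus) != 11 || nchar(box_b_consensus) != 11) {
    stop("Box A and Box B consensus must be 11-mers")
  }
  structure(list(box_a_consensus = toupper(dna(box_a_consensus)),
                 box_b_consensus = toupper(dna(box_b_consensus)),
                 max_mismatches = as.integer(max_mismatches)),
            class = "box_motif_config")
}

# Mismatch count of every window of width nchar(consensus) against an IUPAC
# consensus; N matches anything.
iupac_window_mismatches <- function(sequence, consensus) {
  s <- strsplit(toupper(dna(sequence)), "")[[1]]
  cons <- strsplit(consensus, "")[[1]]
  n <- length(s)
  w <- length(cons)
  if (n < w) return(integer(0))
  allowed <- lapply(cons, function(cl) {
    code <- Biostrings::IUPAC_CODE_MAP[[cl]]
    if (is.null(code)) stop("invalid IUPAC letter in consensus: ", cl)
    strsplit(code, "")[[1]]
  })
  mm <- integer(n - w + 1)
  for (j in seq_len(w)) {
    mm <- mm + !(s[j:(j + n - w)] %in% allowed[[j]])
  }
  mm
}

#' Scan a tRNA gene for Box A and Box B promoter elements
#'
#' Reports all windows within the mismatch budget, best first (fewest
#' mismatches, then 5'-most). When both boxes hit, A-box hits are reported
#' only 5' of the 5'-most B-box hit, reflecting the A-then-B architecture.
#'
#' @param gene_sequence Nucleotide string (DNA or RNA spelling).
#' @param config A [box_motif_config()].
#' @return Tibble with columns `box` (`"A"`/`"B"`), `offset` (1-based window
#'   start) and `mismatches`; zero rows when nothing is found or the sequence
#'   is shorter than 11 nt.
#' @export
find_polIII_boxes <- function(gene_sequence, config = box_motif_config()) {
  hits_for <- function(box, consensus) {
    mm <- iupac_window_mismatches(gene_sequence, consensus)
    keep <- which(mm <= config$max_mismatches)
    tibble(box = rep(box, length(keep)), offset = as.integer(keep),
           mismatches = mm[keep])
  }
  a <- hits_for("A", config$box_a_consensus)
  b <- hits_for("B", config$box_b_consensus)
  if (nrow(a) && nrow(b)) a <- a[a$offset < min(b$offset), , drop = FALSE]
  out <- bind_rows(a, b)
  out[order(out$mismatches, out$offset), , drop = FALSE]
}
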