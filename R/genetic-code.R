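# Genetic-code helpers. Internal alphabet is DNA; codons and anticodons are
# rendered as RNA (U) at reporting boundaries to match the published tables.

#' Convert between DNA and RNA spellings
#'
#' `rna()` rewrites T as U, `dna()` the reverse. Case is preserved.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname rna
#' @export
dna <- function(x) chartr("Uu", "Tt", x)

#' The 61 sense codons of the standard genetic code (RNA spelling)
#'
#' @format Character vector of length 61, alphabetical order.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(rna(names(gc)[gc != "*"]))
}

stop_codons <- function() rna(c("TAA", "TAG", "TGA"))

#' Translate a codon to its amino acid
#'
#' @param codon Character vector of triplets (RNA or DNA spelling).
#' @param three_letter Return three-letter amino-acid codes ("Tyr") instead of
#'   one-letter ("Y")?
#' @return Character vector of amino-acid codes; `"*"`/`"Stp"` for stops.
#' @export
codon_to_aa <- function(codon, three_letter = FALSE) {
  cd <- toupper(dna(codon))
  bad <- !grepl("^[ACGT]{3}$", cd)
  if (any(bad)) {
    stop("not a codon over {A,C,G,U/T}: ", paste(codon[bad], collapse = ", "))
  }
  aa <- unname(Biostrings::GENETIC_CODE[cd])
  if (three_letter) aa <- aa1_to_aa3(aa)
  aa
}

#' @rdname codon_to_aa
#' @param aa One-letter amino-acid codes.
#' @export
aa1_to_aa3 <- function(aa) {
  code <- c(Biostrings::AMINO_ACID_CODE, "*" = "Stp")
  unname(code[aa])
}

aa3_to_aa1 <- function(aa3) {
  code <- c(Biostrings::AMINO_ACID_CODE, "*" = "Stp")
  unname(setNames(names(code), code)[aa3])
}

#' Reverse complement of a nucleotide string
#'
#' Output spelling (DNA/RNA) follows the input: an input containing U (and no
#' T) is treated and returned as RNA.
#'
#' @param x Character vector of nucleotide strings over A, C, G, T/U.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    is_rna <- grepl("[Uu]", s) && !grepl("[Tt]", s)
    s_dna <- toupper(dna(s))
    if (!grepl("^[ACGT]*$", s_dna)) {
      stop("non-ACGU/T characters in sequence: ", s)
    }
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s_dna)))
    if (is_rna) rna(out) else out
  }, character(1), USE.NAMES = FALSE)
}
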