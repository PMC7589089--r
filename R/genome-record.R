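# Uniform in-memory model for an annotated single-contig genome.
#
# Coordinates are 1-based inclusive throughout (GenBank convention).
# Minus-strand features keep plus-strand coordinates; sequence retrieval
# reverse-complements on demand. Features of unknown kind are retained as
# kind "other" because cluster interruption logic needs them.

FEATURE_KINDS <- c("tRNA", "CDS", "other")

#' Build the feature table of a genome record
#'
#' Normalises a data frame of genomic features into the canonical feature
#' tibble: one row per feature with 1-based inclusive coordinates, sorted by
#' start (ties broken by end), exon sub-intervals as a list column of
#' `data.frame(start, end)` in plus-strand order.
#'
#' @param feature_id Character, unique per feature.
#' @param kind One of `"tRNA"`, `"CDS"`, `"other"`.
#' @param start,end Integer positions, `1 <= start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param product,anticodon Optional qualifier strings (`NA` when absent);
#'   anticodon is stored as annotated (DNA, coding strand, 5'->3').
#' @param pseudo Logical pseudogene flag.
#' @param exons Optional list of `data.frame(start, end)` exon sub-intervals;
#'   `NULL` entries mean single-exon.
#' @return A tibble with one row per feature.
#' @export
feature_table <- function(feature_id = character(), kind = character(),
                          start = integer(), end = integer(),
                          strand = character(), product = NA_character_,
                          anticodon = NA_character_, pseudo = FALSE,
                          exons = NULL) {
  n <- length(start)
  if (is.null(exons)) exons <- rep(list(NULL), n)
  tbl <- tibble(
    feature_id = as.character(feature_id),
    kind = as.character(kind),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    product = rep_len(as.character(product), n),
    anticodon = rep_len(as.character(anticodon), n),
    pseudo = rep_len(as.logical(pseudo), n),
    exons = exons
  )
  tbl[order(tbl$start, tbl$end), , drop = FALSE]
}

#' Create an annotated genome record
#'
#' @param id Genome identifier.
#' @param sequence Nucleotide string (DNA alphabet; uppercased on input).
#' @param features Feature tibble as built by [feature_table()].
#' @param clade Clade label, e.g. `"NC64A"`, `"SAG"`, `"Pbi"`, `"host"`,
#'   `"other"`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = feature_table(),
                          clade = "other") {
  sequence <- toupper(as.character(sequence))
  rec <- structure(
    list(id = as.character(id), clade = as.character(clade),
         sequence = sequence, length = nchar(sequence),
         features = features[order(features$start, features$end), ,
                             drop = FALSE]),
    class = "genome_record")
  validate_genome_record(rec)
  rec
}

#' Validate a genome record's invariants
#'
#' Checks length consistency, feature ordering, coordinate bounds, allowed
#' kinds and exon tiling (exon sub-intervals must be disjoint, ordered and lie
#' within their feature span).
#'
#' @param record A `genome_record`.
#' @return The record, invisibly; stops on violation.
#' @export
validate_genome_record <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  if (record$length != nchar(record$sequence)) {
    stop("record length disagrees with sequence length")
  }
  ft <- record$features
  if (nrow(ft) == 0) return(invisible(record))
  if (!all(ft$kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind: ",
         paste(setdiff(ft$kind, FEATURE_KINDS), collapse = ", "))
  }
  if (any(ft$start < 1L) || any(ft$end > record$length) ||
      any(ft$start > ft$end)) {
    stop("feature coordinates outside [1, genome length] or start > end")
  }
  if (is.unsorted(ft$start)) stop("features not sorted by start")
  for (i in seq_len(nrow(ft))) {
    ex <- ft$exons[[i]]
    if (is.null(ex)) next
    if (any(ex$start > ex$end)) stop("exon with start > end")
    if (is.unsorted(ex$start, strictly = TRUE)) stop("exons not ordered")
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exon sub-intervals")
    }
    if (ex$start[1] != ft$start[i] || ex$end[nrow(ex)] != ft$end[i]) {
      stop("exons do not tile the feature span of ", ft$feature_id[i])
    }
  }
  invisible(record)
}

#' Extract features of one kind, genome order preserved
#'
#' @param record A `genome_record`.
#' @param kind `"tRNA"`, `"CDS"` or `"other"`.
#' @return Feature tibble subset, still sorted by start.
#' @export
extract_features <- function(record, kind) {
  kind <- match.arg(kind, FEATURE_KINDS)
  record$features[record$features$kind == kind, , drop = FALSE]
}

#' Retrieve a feature's nucleotide sequence
#'
#' Returns the coding-strand sequence 5'->3': exon sub-intervals are joined
#' when `spliced = TRUE`, and minus-strand features are reverse-complemented.
#'
#' @param record A `genome_record`.
#' @param feature One row of the record's feature tibble (list or one-row
#'   tibble).
#' @param spliced Join exons (drop introns)? If `FALSE` the full span is
#'   returned.
#' @return A character scalar.
#' @export
feature_sequence <- function(record, feature, spliced = TRUE) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1)
    feature <- as.list(feature)
    feature$exons <- feature$exons[[1]]
  }
  ex <- feature$exons
  if (!spliced || is.null(ex)) {
    ex <- data.frame(start = feature$start, end = feature$end)
  }
  parts <- substring(record$sequence, ex$start, ex$end)
  s <- paste(parts, collapse = "")
  if (identical(feature$strand, "-")) s <- reverse_complement(s)
  s
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (clade %s): %s nt, %d features\n",
              x$id, x$clade, format(x$length, big.mark = ","),
              nrow(x$features)))
  if (nrow(x$features) > 0) {
    print(table(x$features$kind))
  }
  invisible(x)
}
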