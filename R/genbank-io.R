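# Single-record GenBank flat-file reader and writer for the feature subset
# the pipeline consumes (tRNA, CDS; everything else kept as kind "other").
# The writer emits deterministic field order so that write -> read is an
# identity on (kind, coordinates, strand, exons, product, anticodon, pseudo).

#' Read a single-record GenBank flat file
#'
#' Captures every tRNA and CDS feature (all other feature keys are kept with
#' kind `"other"`), including `join()` exon structure and the `/pseudo`,
#' `/product` and `/anticodon` qualifiers. The `source` feature describes the
#' record itself and is not treated as an annotation.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @param clade Clade label to attach (defaults to a `/note="clade:..."` tag
#'   on the source feature when present, else `"other"`).
#' @return A [genome_record()].
#' @export
read_genbank <- function(path, clade = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "LOCUS")) {
    stop("malformed GenBank file (line 1): expected LOCUS header in ", path)
  }
  if (sum(startsWith(lines, "LOCUS")) > 1) {
    stop("multi-record GenBank file: split it and process one record at a time")
  }
  feat_at <- which(startsWith(lines, "FEATURES"))
  orig_at <- which(startsWith(lines, "ORIGIN"))
  if (length(feat_at) != 1 || length(orig_at) != 1 || orig_at < feat_at) {
    stop("malformed GenBank file: need one FEATURES and one ORIGIN section")
  }

  id <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "[ \t]+")[[1]][1]

  seq_lines <- lines[(orig_at + 1):length(lines)]
  seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
  sequence <- toupper(gsub("[ 0-9/]", "", paste(seq_lines, collapse = "")))

  fl <- lines[(feat_at + 1):(orig_at - 1)]
  starts <- which(grepl("^ {5}\\S", fl))
  rows <- list()
  src_clade <- NA_character_
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1 else length(fl)
    block <- fl[from:to]
    key <- sub("^ +(\\S+).*$", "\\1", block[1])
    body <- sub("^ {5}\\S+ +", "", block[1])
    rest <- trimws(block[-1])
    # location may continue until the first qualifier line
    qual_at <- which(startsWith(rest, "/"))
    loc_extra <- if (length(qual_at)) head(rest, qual_at[1] - 1) else rest
    quals <- if (length(qual_at)) rest[qual_at[1]:length(rest)] else character()
    loc <- gsub(" ", "", paste(c(body, loc_extra), collapse = ""))
    parsed <- parse_genbank_location(loc, line = feat_at + from)

    qual_txt <- paste(quals, collapse = "\n")
    product <- match_qualifier(qual_txt, "product")
    pseudo <- grepl("(^|\n)/pseudo(\n|$)", qual_txt)
    anticodon <- NA_character_
    ac_raw <- match_qualifier(qual_txt, "anticodon", quoted = FALSE)
    if (!is.na(ac_raw)) {
      m <- regmatches(ac_raw, regexpr("seq:[acgtuACGTU]+", ac_raw))
      if (length(m)) anticodon <- toupper(dna(sub("seq:", "", m)))
    }
    if (key == "source") {
      note <- match_qualifier(qual_txt, "note")
      if (!is.na(note) && grepl("^clade:", note)) {
        src_clade <- sub("^clade:", "", note)
      }
      next
    }
    rows[[length(rows) + 1]] <- list(
      feature_id = match_qualifier(qual_txt, "locus_tag"),
      kind = if (key %in% c("tRNA", "CDS")) key else "other",
      start = parsed$start, end = parsed$end, strand = parsed$strand,
      product = product, anticodon = anticodon, pseudo = pseudo,
      exons = list(parsed$exons))
  }
  ft <- if (length(rows)) {
    tb <- bind_rows(lapply(rows, function(r) {
      tibble(feature_id = r$feature_id %||% NA_character_, kind = r$kind,
             start = r$start, end = r$end, strand = r$strand,
             product = r$product, anticodon = r$anticodon, pseudo = r$pseudo,
             exons = r$exons)
    }))
    tb$feature_id[is.na(tb$feature_id)] <-
      sprintf("feat%03d", which(is.na(tb$feature_id)))
    tb[order(tb$start, tb$end), , drop = FALSE]
  } else {
    feature_table()
  }
  genome_record(id, sequence, ft,
                clade = clade %||% (if (is.na(src_clade)) "other" else src_clade))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

match_qualifier <- function(txt, name, quoted = TRUE) {
  pat <- if (quoted) sprintf('/%s="([^"]*)"', name) else sprintf("/%s=(\\S+)", name)
  m <- regmatches(txt, regexec(pat, txt))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}

parse_genbank_location <- function(loc, line = NA) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ok <- grepl("^[0-9]+(\\.\\.[0-9]+)?$", parts)
  if (!length(parts) || !all(ok)) {
    stop("malformed GenBank location near line ", line, ": ", loc)
  }
  se <- t(vapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(xs) == 1) xs <- c(xs, xs)
    xs
  }, integer(2)))
  ex <- data.frame(start = se[, 1], end = se[, 2])
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  list(start = min(ex$start), end = max(ex$end), strand = strand,
       exons = if (nrow(ex) > 1) ex else NULL)
}

format_genbank_location <- function(start, end, strand, exons) {
  loc <- if (is.null(exons)) {
    sprintf("%d..%d", start, end)
  } else {
    sprintf("join(%s)",
            paste(sprintf("%d..%d", exons$start, exons$end), collapse = ","))
  }
  if (identical(strand, "-")) loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a genome record as a GenBank flat file
#'
#' `read_genbank(write_genbank(r))` reproduces `r`'s feature kinds,
#' coordinates, strands, exon structure and qualifiers.
#'
#' @param record A [genome_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  validate_genome_record(record)
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  out <- function(...) writeLines(sprintf(...), con, sep = "\n")

  out("LOCUS       %s %d bp    DNA     linear   UNA 01-JAN-2000",
      record$id, record$length)
  out("DEFINITION  %s synthetic or derived record.", record$id)
  out("ACCESSION   %s", record$id)
  out("FEATURES             Location/Qualifiers")
  out("     source          1..%d", record$length)
  out("                     /organism=\"%s\"", record$id)
  out("                     /note=\"clade:%s\"", record$clade)
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    key <- if (ft$kind[i] %in% c("tRNA", "CDS")) ft$kind[i] else "misc_feature"
    loc <- format_genbank_location(ft$start[i], ft$end[i], ft$strand[i],
                                   ft$exons[[i]])
    out("     %-15s %s", key, loc)
    out("                     /locus_tag=\"%s\"", ft$feature_id[i])
    if (!is.na(ft$product[i])) {
      out("                     /product=\"%s\"", ft$product[i])
    }
    if (!is.na(ft$anticodon[i])) {
      pos <- anticodon_genomic_pos(ft[i, ])
      out("                     /anticodon=(pos:%d..%d,aa:%s,seq:%s)",
          pos[1], pos[2],
          anticodon_aa3(ft$anticodon[i]), tolower(ft$anticodon[i]))
    }
    if (isTRUE(ft$pseudo[i])) out("                     /pseudo")
  }
  out("ORIGIN")
  seq <- tolower(record$sequence)
  pos <- seq(1, nchar(seq), by = 60)
  for (p in pos) {
    chunk <- substring(seq, p, min(p + 59, nchar(seq)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out("%9d %s", p, paste(blocks, collapse = " "))
  }
  out("//")
  invisible(path)
}

# Genomic coordinates of anticodon positions 34-36, given exon structure.
anticodon_genomic_pos <- function(feature_row) {
  ex <- feature_row$exons[[1]]
  if (is.null(ex)) ex <- data.frame(start = feature_row$start,
                                    end = feature_row$end)
  strand <- feature_row$strand
  widths <- ex$end - ex$start + 1
  # exonic offsets 34..36 along the coding strand
  target <- 34:36
  if (strand == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    widths <- rev(widths)
  }
  cum <- cumsum(widths)
  genomic <- vapply(target, function(tp) {
    j <- which(cum >= tp)[1]
    if (is.na(j)) return(NA_real_)
    within <- tp - (if (j > 1) cum[j - 1] else 0)
    as.numeric(if (strand == "+") ex$start[j] + within - 1
               else ex$end[j] - within + 1)
  }, numeric(1))
  if (anyNA(genomic)) {
    # feature too short to host positions 34-36; fall back to its start
    return(c(feature_row$start, feature_row$start + 2L))
  }
  as.integer(range(genomic))
}

anticodon_aa3 <- function(anticodon_dna) {
  aa <- tryCatch(codon_to_aa(reverse_complement(anticodon_dna),
                             three_letter = TRUE),
                 error = function(e) "Xaa")
  if (is.na(aa)) "Xaa" else aa
}
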