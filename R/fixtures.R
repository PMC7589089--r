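# Packaged machine-readable transcriptions of the published chlorovirus tRNA
# and codon-usage tables. The transcriptions carry the printed values
# untouched (including the suspect GAU ratio and the printed totals); every
# known discrepancy and transcription judgment call is documented in the
# errata sidecar fixture, which is itself loadable.

FIXTURE_FILES <- c(
  table1_nc64a = "table1_nc64a.tsv",
  table2_sag = "table2_sag.tsv",
  table3_pbi = "table3_pbi.tsv",
  table4_presence = "table4_presence.tsv",
  table5_codon_usage = "table5_codon_usage.tsv",
  fixture_errata = "fixture_errata.tsv")

fixture_path <- function(file, dir = NULL) {
  p <- if (is.null(dir)) {
    system.file("extdata", file, package = "chlorotrna")
  } else {
    f <- file.path(dir, file)
    if (file.exists(f)) f else ""
  }
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

#' Load a packaged table fixture
#'
#' Fixtures are tab-separated transcriptions of the published per-clade tRNA
#' cluster tables (long format: one row per gene with identity, copy index,
#' trailing spacer, intron/orphan/substitution flags and the printed total),
#' the cross-clade presence table, and the codon-usage comparison (61 sense
#' codons with the three printed frequency columns and the printed ratio).
#' Each file's MD5 is verified against the packaged checksum manifest before
#' parsing; fixtures are data, not code.
#'
#' @param name One of `"table1_nc64a"`, `"table2_sag"`, `"table3_pbi"`,
#'   `"table4_presence"`, `"table5_codon_usage"`, `"fixture_errata"`.
#' @param dir Override the fixture directory (testing hook; default is the
#'   package's `extdata`).
#' @return A tibble; structure validated per fixture.
#' @export
load_fixture <- function(name, dir = NULL) {
  name <- match.arg(name, names(FIXTURE_FILES))
  file <- FIXTURE_FILES[[name]]
  path <- fixture_path(file, dir)
  manifest <- read.delim(fixture_path("fixture_checksums.tsv", dir),
                         stringsAsFactors = FALSE)
  expected <- manifest$md5[manifest$file == file]
  if (length(expected) != 1) stop("fixture missing from checksum manifest: ", file)
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected)) {
    stop("fixture checksum mismatch for ", file,
         " (expected ", expected, ", got ", actual, ")")
  }
  tbl <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_fixture(name, tbl)
  tbl
}

validate_fixture <- function(name, tbl) {
  if (name %in% c("table1_nc64a", "table2_sag", "table3_pbi")) {
    need <- c("virus", "clade", "position", "amino_acid", "codon", "copy",
              "spacer_after", "pseudogene", "intron", "orphan", "note",
              "total_printed")
    if (!all(need %in% names(tbl))) stop("malformed cluster-table fixture")
    counts <- tapply(tbl$position, tbl$virus, length)
    totals <- tapply(tbl$total_printed, tbl$virus, unique)
    if (!all(counts == unlist(totals))) {
      stop("fixture row counts disagree with printed totals")
    }
  } else if (name == "table5_codon_usage") {
    if (nrow(tbl) != 61) stop("codon-usage fixture must have 61 sense codons")
    if (!setequal(tbl$codon, sense_codons())) {
      stop("codon-usage fixture codons are not the 61 sense codons")
    }
  } else if (name == "table4_presence") {
    if (!all(c("label", "amino_acid", "codon", "nc64a", "sag", "pbi") %in%
             names(tbl))) {
      stop("malformed presence fixture")
    }
  }
  invisible(tbl)
}

#' Load the three per-clade cluster tables as one cohort
#'
#' @return Long tibble covering all 41 genomes (147 + 137 + 123 genes), with
#'   `identity_known = TRUE` and a `genome` column aliasing `virus`.
#' @export
load_cluster_fixtures <- function() {
  tbl <- bind_rows(load_fixture("table1_nc64a"), load_fixture("table2_sag"),
                   load_fixture("table3_pbi"))
  tbl$genome <- tbl$virus
  tbl$identity_known <- TRUE
  tbl
}

#' Codon usage tables from the published comparison
#'
#' @return List with `codon_usage_table` objects `pbcv1`, `an69c`, `host`,
#'   plus the raw fixture tibble as `fixture`.
#' @export
load_codon_usage_fixture <- function() {
  t5 <- load_fixture("table5_codon_usage")
  col <- function(x, src) {
    codon_usage_from_percent(setNames(t5[[x]], t5$codon), source = src)
  }
  list(pbcv1 = col("pbcv1", "PBCV-1"), an69c = col("an69c", "AN69C"),
       host = col("host", "C. variabilis NC64A"), fixture = t5)
}

#' Recognized-codon sets of the two viruses in the codon-usage comparison
#'
#' Distinct cognate codons of each virus's tRNA complement, read off the
#' per-clade cluster fixture.
#'
#' @return List of character vectors `pbcv1`, `an69c` (RNA codons).
#' @export
fixture_recognized_codons <- function() {
  t1 <- load_fixture("table1_nc64a")
  list(pbcv1 = sort(unique(t1$codon[t1$virus == "PBCV-1"])),
       an69c = sort(unique(t1$codon[t1$virus == "AN69C"])))
}
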