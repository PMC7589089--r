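# Codon usage tables, the mean-virus/host ratio statistic and the tRNA
# favorability classification.
#
# Frequencies are percentages over the 61 sense codons with stops excluded;
# that is the only reading under which a 61-row published table is
# self-consistent. The ratio is mean-then-divide: R_c = mean_v f_{v,c} / h_c,
# per the table footnote ("average codon usage of the two viruses divided by
# codon usage of the host"); with a single virus this degrades gracefully to
# a plain per-virus ratio.

#' Build a codon usage table from CDS sequences
#'
#' Codons are counted in frame 0. A terminal stop codon is excluded; internal
#' stop codons and codons containing non-ACGT characters are not counted
#' toward the sense-codon total but are reported in the `qc` attribute.
#' Percentages are over counted sense codons and sum to 100 within 1e-9.
#'
#' @param cds_sequences Character vector of CDS nucleotide strings (DNA or
#'   RNA spelling), each of length >= 3.
#' @param source Label for the genome/organism of origin.
#' @return A `codon_usage_table`: tibble with `codon` (RNA), `amino_acid`,
#'   `count`, `freq` (percent), plus attributes `total_codons`, `source`,
#'   `qc`.
#' @export
codon_frequencies <- function(cds_sequences, source = "") {
  if (!length(cds_sequences)) stop("no CDS sequences supplied")
  if (any(nchar(cds_sequences) < 3)) stop("each CDS must be at least 3 nt")
  codons <- unlist(lapply(cds_sequences, function(s) {
    s <- toupper(dna(s))
    n3 <- (nchar(s) %/% 3) * 3
    cs <- substring(s, seq(1, n3 - 2, by = 3), seq(3, n3, by = 3))
    if (length(cs) && cs[length(cs)] %in% stop_codons_dna()) {
      cs <- cs[-length(cs)]
    }
    cs
  }))
  ambiguous <- !grepl("^[ACGT]{3}$", codons)
  internal_stop <- !ambiguous & codons %in% stop_codons_dna()
  sense <- codons[!ambiguous & !internal_stop]
  counts <- table(factor(rna(sense), levels = sense_codons()))
  total <- sum(counts)
  if (total == 0) stop("no sense codons counted")
  tbl <- tibble(codon = sense_codons(),
                amino_acid = codon_to_aa(sense_codons()),
                count = as.integer(counts),
                freq = 100 * as.numeric(counts) / total)
  new_codon_usage_table(tbl, total_codons = total, source = source,
                        qc = list(internal_stops = sum(internal_stop),
                                  ambiguous_codons = sum(ambiguous)))
}

stop_codons_dna <- function() c("TAA", "TAG", "TGA")

new_codon_usage_table <- function(tbl, total_codons, source, qc = list()) {
  structure(tbl, total_codons = total_codons, source = source, qc = qc,
            class = c("codon_usage_table", class(tbl)))
}

#' Build a codon usage table from printed percentages
#'
#' For published tables the 61 percentages are taken as given; sums are only
#' required to be near 100 (printed rounding).
#'
#' @param freqs Named numeric vector: RNA codon -> percent frequency, all 61
#'   sense codons present.
#' @param source Label.
#' @return A `codon_usage_table` with `count = NA`.
#' @export
codon_usage_from_percent <- function(freqs, source = "") {
  missing <- setdiff(sense_codons(), names(freqs))
  if (length(missing)) {
    stop("missing codons: ", paste(missing, collapse = ", "))
  }
  if (any(freqs < 0)) stop("negative frequency")
  s <- sum(freqs[sense_codons()])
  if (s < 95 || s > 100.5) {
    stop("frequencies sum to ", round(s, 2), ", expected ~100")
  }
  tbl <- tibble(codon = sense_codons(),
                amino_acid = codon_to_aa(sense_codons()),
                count = NA_integer_,
                freq = as.numeric(freqs[sense_codons()]))
  new_codon_usage_table(tbl, total_codons = NA_integer_, source = source)
}

#' GC content of a sequence or genome record
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguous bases are excluded from both
#' numerator and denominator.
#'
#' @param x Nucleotide string or a [genome_record()].
#' @return Percent GC.
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "genome_record")) x$sequence else toupper(dna(x))
  if (!nzchar(s)) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) stop("sequence contains no unambiguous A/C/G/T bases")
  100 * sum(counts[c("C", "G")]) / denom
}

#' The mean-virus/host codon usage ratio statistic
#'
#' For every sense codon c, `R_c = mean_v f_{v,c} / h_c`: the virus
#' frequencies are averaged first, then divided by the host frequency.
#' `R_c > 1` favors the virus, `R_c < 1` the host. Codons with host
#' frequency 0 get an undefined (NA) ratio and are flagged, never infinite.
#'
#' @param virus_tables A `codon_usage_table` or list of them (>= 1).
#' @param host_table A `codon_usage_table`.
#' @return A `cub_ratio_table`: tibble with `codon`, `amino_acid`,
#'   `f_virus_mean`, `f_host`, `ratio`, `favored` in
#'   `{"virus","host","boundary","undefined"}`.
#' @export
cub_ratio <- function(virus_tables, host_table) {
  if (inherits(virus_tables, "codon_usage_table")) {
    virus_tables <- list(virus_tables)
  }
  if (!length(virus_tables)) stop("at least one virus table required")
  stopifnot(inherits(host_table, "codon_usage_table"))
  vf <- vapply(virus_tables, function(t) {
    stopifnot(inherits(t, "codon_usage_table"))
    setNames(t$freq, t$codon)[sense_codons()]
  }, numeric(61))
  m <- rowMeans(matrix(vf, nrow = 61))
  h <- setNames(host_table$freq, host_table$codon)[sense_codons()]
  ratio <- ifelse(h > 0, m / h, NA_real_)
  favored <- dplyr::case_when(
    is.na(ratio) ~ "undefined",
    ratio > 1 ~ "virus",
    ratio < 1 ~ "host",
    TRUE ~ "boundary")
  out <- tibble(codon = sense_codons(),
                amino_acid = codon_to_aa(sense_codons()),
                f_virus_mean = unname(m), f_host = unname(h),
                ratio = unname(ratio), favored = favored)
  structure(out, n_virus = length(virus_tables),
            class = c("cub_ratio_table", class(out)))
}

#' Round half-up for table presentation
#'
#' Published ratios are printed to 2 decimals with halves rounded up (12.695
#' prints as 12.70); base `round()` rounds half to even, so presentation uses
#' this helper. Comparisons in analysis code stay on unrounded values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Most common synonymous codon per amino acid
#'
#' @param table A `codon_usage_table`.
#' @return Tibble with `amino_acid`, `codon` (argmax; several rows on ties),
#'   `freq`, `tie` flag.
#' @export
preferred_codons <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  tbl <- as_tibble(table)[, c("amino_acid", "codon", "freq")]
  rows <- lapply(split(tbl, tbl$amino_acid), function(d) {
    d <- d[d$freq == max(d$freq), , drop = FALSE]
    d$tie <- nrow(d) > 1
    d
  })
  out <- bind_rows(rows)
  out[order(out$amino_acid, out$codon), c("amino_acid", "codon", "freq", "tie")]
}

#' Favorability classification parameters
#'
#' @param threshold Ratio threshold tau (> 0); a codon assists the virus when
#'   `R_c > tau`. `R_c == tau` is labeled `boundary`, not assisting.
#' @param counting `"distinct_codons"` (default; one vote per recognized
#'   codon, the reading under which "11 tRNAs but only 7 help" holds) or
#'   `"per_gene"` (each gene votes; for sensitivity analysis).
#' @param use_wobble Expand recognition sets by [wobble_recognition_set()]?
#' @param apply_tils Recode Met/CAU genes to read AUA before classifying?
#' @return A `favorability_params` list.
#' @export
favorability_params <- function(threshold = 1.0,
                                counting = c("distinct_codons", "per_gene"),
                                use_wobble = FALSE, apply_tils = FALSE) {
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(threshold = threshold, counting = match.arg(counting),
                 use_wobble = isTRUE(use_wobble),
                 apply_tils = isTRUE(apply_tils)),
            class = "favorability_params")
}

#' Classify which virus tRNAs help overcome host codon usage bias
#'
#' Assembles the recognized-codon set of a tRNA inventory (strict cognate
#' codons by default; wobble and TilS expansions by parameter) and labels
#' each codon `assisting` when its virus/host ratio exceeds the threshold,
#' else `neutral` (`boundary` at equality). Pseudogenes and identity-unknown
#' tRNAs are excluded with a warning but reported in the gene count.
#'
#' @param inventory Inventory tibble ([build_inventory()] or equivalent with
#'   `amino_acid`, `codon`, `anticodon`, `pseudogene`, `identity_known`).
#' @param ratios A `cub_ratio_table`.
#' @param params A [favorability_params()].
#' @return A `favorability_report` list: `codons` tibble (codon, ratio,
#'   label, n_genes), `n_genes`, `n_genes_classified`, `n_distinct_codons`,
#'   `n_assisting` and the params used.
#' @export
classify_favorability <- function(inventory, ratios,
                                  params = favorability_params()) {
  stopifnot(inherits(ratios, "cub_ratio_table"))
  n_total <- nrow(inventory)
  usable <- inventory
  if ("identity_known" %in% names(usable)) {
    usable <- usable[usable$identity_known %in% TRUE, , drop = FALSE]
  }
  if ("pseudogene" %in% names(usable)) {
    usable <- usable[!(usable$pseudogene %in% TRUE), , drop = FALSE]
  }
  if (nrow(usable) < n_total) {
    warning(n_total - nrow(usable),
            " pseudogene or identity-unknown tRNA(s) excluded from ",
            "favorability classification")
  }
  gene_sets <- lapply(seq_len(nrow(usable)), function(i) {
    g <- usable[i, ]
    if (params$apply_tils && identical(g$amino_acid, "Met") &&
        identical(g$codon, "AUG") && identical(g$anticodon, "CAU")) {
      return("AUA")
    }
    if (params$use_wobble && !is.na(g$anticodon)) {
      wobble_recognition_set(g$anticodon)
    } else {
      g$codon
    }
  })
  rt <- setNames(ratios$ratio, ratios$codon)
  label_of <- function(r) {
    if (is.na(r)) "undefined"
    else if (r > params$threshold) "assisting"
    else if (r == params$threshold) "boundary"
    else "neutral"
  }
  codons <- sort(unique(unlist(gene_sets)))
  n_genes_per <- vapply(codons, function(cd) {
    sum(vapply(gene_sets, function(s) cd %in% s, logical(1)))
  }, integer(1))
  cod_tbl <- tibble(codon = codons,
                    amino_acid = codon_to_aa(codons),
                    ratio = unname(rt[codons]),
                    label = vapply(unname(rt[codons]), label_of, character(1)),
                    n_genes = unname(n_genes_per))
  n_assisting <- if (params$counting == "distinct_codons") {
    sum(cod_tbl$label == "assisting")
  } else {
    sum(cod_tbl$n_genes[cod_tbl$label == "assisting"])
  }
  structure(list(codons = cod_tbl, n_genes = n_total,
                 n_genes_classified = nrow(usable),
                 n_distinct_codons = nrow(cod_tbl),
                 n_assisting = n_assisting, params = params),
            class = "favorability_report")
}

#' @export
print.favorability_report <- function(x, ...) {
  cat(sprintf(
    "<favorability_report> %d genes (%d classified), %d distinct codons, %d assisting (tau = %g, %s)\n",
    x$n_genes, x$n_genes_classified, x$n_distinct_codons, x$n_assisting,
    x$params$threshold, x$params$counting))
  print(as.data.frame(x$codons))
  invisible(x)
}

#' The TilS benefit: the AUA ratio
#'
#' The recoded tRNA-Met reads the isoleucine codon AUA, which is 12-13 times
#' more common in the NC64A viruses than in their host; this reports the AUA
#' virus/host ratio and its assisting/neutral label.
#'
#' @param ratios A `cub_ratio_table`.
#' @param threshold Assisting threshold (default 1).
#' @return List with `codon = "AUA"`, `ratio`, `label`.
#' @export
tils_benefit <- function(ratios, threshold = 1.0) {
  stopifnot(inherits(ratios, "cub_ratio_table"))
  r <- ratios$ratio[ratios$codon == "AUA"]
  if (is.na(r)) stop("AUA ratio undefined (host AUA frequency is 0)")
  list(codon = "AUA", ratio = r,
       label = if (r > threshold) "assisting"
               else if (r == threshold) "boundary" else "neutral")
}
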