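# Cross-genome and cross-clade comparison of tRNA gene complements.
#
# Identity granularity is (amino acid, cognate codon) — the column semantics
# of the published per-clade tables. Unique-per-clade counts are additionally
# reported at gene-column granularity (a clade can carry two distinct gene
# columns of the same identity, as the Pbi clade does for Thr-ACG), which is
# how the published common/unique bookkeeping counts.

# paste0() recycles zero-length inputs against constants; this keeps empty in
# -> empty out for identity keys.
identity_key <- function(amino_acid, codon) {
  if (!length(amino_acid)) return(character(0))
  paste0(amino_acid, "-", codon)
}

#' Presence/absence matrix of tRNA identities across genomes
#'
#' @param inventories Either a named list of inventory tibbles (names =
#'   genome ids) or one long tibble with a `genome` column. Rows need
#'   `amino_acid`, `codon` and optionally `pseudogene`, `copy`.
#' @param clade_map Named character vector genome -> clade; defaults to the
#'   `clade` column when present.
#' @param include_pseudogenes Count pseudogenes as presence (default TRUE,
#'   matching the published presence bookkeeping)?
#' @return A `presence_matrix`: logical matrix identities x genomes with
#'   attributes `identity` (tibble amino_acid/codon), `clade_map`, and
#'   `column_counts` (clade x identity gene-column multiplicity, from the
#'   `copy` column when available, else 0/1 presence).
#' @export
presence_matrix <- function(inventories, clade_map = NULL,
                            include_pseudogenes = TRUE) {
  long <- if (is.data.frame(inventories)) {
    inventories
  } else {
    bind_rows(lapply(names(inventories), function(g) {
      d <- inventories[[g]]
      d$genome <- g
      d
    }))
  }
  if (is.null(clade_map)) {
    if (!"clade" %in% names(long)) stop("clade_map required (no clade column)")
    clade_map <- vapply(split(long$clade, long$genome), function(x) x[1],
                        character(1))
  }
  if ("identity_known" %in% names(long)) {
    long <- long[long$identity_known %in% TRUE, , drop = FALSE]
  } else {
    long <- long[!is.na(long$codon), , drop = FALSE]
  }
  if (!include_pseudogenes && "pseudogene" %in% names(long)) {
    long <- long[!(long$pseudogene %in% TRUE), , drop = FALSE]
  }
  ids <- unique(long[, c("amino_acid", "codon")])
  ids <- ids[order(ids$amino_acid, ids$codon), , drop = FALSE]
  key <- identity_key(ids$amino_acid, ids$codon)
  genomes <- names(clade_map)
  m <- matrix(FALSE, nrow = nrow(ids), ncol = length(genomes),
              dimnames = list(key, genomes))
  long_key <- identity_key(long$amino_acid, long$codon)
  for (j in seq_along(genomes)) {
    m[unique(long_key[long$genome == genomes[j]]), j] <- TRUE
  }
  clades <- sort(unique(unname(clade_map)))
  cc <- matrix(0L, nrow = length(clades), ncol = nrow(ids),
               dimnames = list(clades, key))
  has_copy <- "copy" %in% names(long)
  for (cl in clades) {
    d <- long[clade_map[long$genome] == cl, , drop = FALSE]
    dk <- identity_key(d$amino_acid, d$codon)
    for (k in unique(dk)) {
      cc[cl, k] <- if (has_copy) {
        length(unique(d$copy[dk == k]))
      } else {
        1L
      }
    }
  }
  structure(m, identity = ids, clade_map = clade_map, column_counts = cc,
            class = c("presence_matrix", "matrix", "array"))
}

#' Shared and unique tRNA identities across clades
#'
#' An identity is clade-present when any member genome carries it.
#' `common_all_clades` is the intersection over all clades;
#' `unique_per_clade` the identities present in exactly one clade;
#' `shared_pairs` those in exactly two. `unique_gene_counts` counts unique
#' identities at gene-column granularity (an identity carried as two distinct
#' gene columns within the clade counts twice), which is the granularity of
#' the published unique-per-clade counts.
#'
#' @param matrix A [presence_matrix()].
#' @return A `shared_unique_summary` list.
#' @export
clade_shared_unique <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  clade_map <- attr(matrix, "clade_map")
  cc <- attr(matrix, "column_counts")
  clades <- sort(unique(unname(clade_map)))
  if (length(clades) < 2) {
    warning("fewer than two clades: everything is clade-unique")
  }
  if (!all(unname(clade_map) %in% rownames(cc))) {
    stop("unknown clade label in clade_map")
  }
  clade_present <- lapply(clades, function(cl) {
    cols <- names(clade_map)[clade_map == cl]
    rownames(matrix)[rowSums(matrix[, cols, drop = FALSE]) > 0]
  })
  names(clade_present) <- clades
  n_clades_with <- Reduce(`+`, lapply(clade_present, function(s) {
    as.integer(rownames(matrix) %in% s)
  }))
  ids <- rownames(matrix)
  common_all <- if (length(clades) >= 2) {
    ids[n_clades_with == length(clades)]
  } else {
    character(0)
  }
  unique_per_clade <- lapply(clades, function(cl) {
    ids[n_clades_with == 1 & ids %in% clade_present[[cl]]]
  })
  names(unique_per_clade) <- clades
  pairs <- if (length(clades) >= 2) {
    utils::combn(clades, 2, simplify = FALSE)
  } else {
    list()
  }
  shared_pairs <- lapply(pairs, function(p) {
    ids[n_clades_with == 2 & ids %in% clade_present[[p[1]]] &
          ids %in% clade_present[[p[2]]]]
  })
  names(shared_pairs) <- vapply(pairs, paste, character(1), collapse = ":")
  unique_gene_counts <- vapply(clades, function(cl) {
    u <- unique_per_clade[[cl]]
    if (!length(u)) 0L else sum(cc[cl, u])
  }, integer(1))
  structure(list(common_all_clades = common_all,
                 unique_per_clade = unique_per_clade,
                 shared_pairs = shared_pairs,
                 unique_gene_counts = unique_gene_counts,
                 clade_present = clade_present),
            class = "shared_unique_summary")
}

#' Gene-order similarity of two tRNA clusters
#'
#' Normalized longest-common-subsequence score over identity labels:
#' `2 * LCS(a, b) / (|a| + |b|)`, in the unit interval; 1 for identical orders, 0 for
#' label-disjoint orders. A quantitative stand-in for the qualitative
#' within-clade synteny observation.
#'
#' @param order_a,order_b Character vectors of identity labels.
#' @return Similarity score between 0 and 1.
#' @export
gene_order_similarity <- function(order_a, order_b) {
  na <- length(order_a)
  nb <- length(order_b)
  if (na + nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  L <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      L[i + 1, j + 1] <- if (order_a[i] == order_b[j]) {
        L[i, j] + 1L
      } else {
        max(L[i, j + 1], L[i + 1, j])
      }
    }
  }
  2 * L[na + 1, nb + 1] / (na + nb)
}

#' Concatenate marker tRNA gene sequences across genomes
#'
#' Extracts the spliced sequence of each marker identity from each genome and
#' concatenates them in the given order (the input to phylogenetic marker
#' analysis; alignment and tree building are external). Genomes missing any
#' marker are skipped with a warning; duplicate copies use the first in
#' genome order, with a warning.
#'
#' @param genomes List of [genome_record()] objects.
#' @param markers Character vector of cognate codons (RNA) identifying the
#'   markers, e.g. `c("GGA", "UAC", "AGA")` for tRNA-Gly/Tyr/Arg.
#' @param file Optional FASTA output path.
#' @return A [Biostrings::DNAStringSet] of concatenated sequences (one per
#'   retained genome).
#' @export
concatenate_markers <- function(genomes, markers, file = NULL) {
  if (!length(markers)) stop("empty marker list")
  seqs <- character()
  for (rec in genomes) {
    inv <- build_inventory(rec)
    parts <- character(length(markers))
    ok <- TRUE
    for (k in seq_along(markers)) {
      hit <- which(inv$codon %in% markers[k] & !(inv$pseudogene %in% TRUE))
      if (!length(hit)) {
        warning("genome ", rec$id, " lacks marker ", markers[k],
                "; skipped from concatenation")
        ok <- FALSE
        break
      }
      if (length(hit) > 1) {
        warning("genome ", rec$id, " has ", length(hit), " copies of marker ",
                markers[k], "; using the first in genome order")
      }
      parts[k] <- inv$sequence[hit[1]]
    }
    if (ok) seqs[rec$id] <- paste(parts, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  if (!is.null(file)) Biostrings::writeXStringSet(out, file, width = 70)
  out
}

#' Cohort-level summary statistics
#'
#' @param inventory_long Long tibble with one row per tRNA gene and columns
#'   `genome`, `clade`, `amino_acid`, `codon`, optionally `strand`,
#'   `pseudogene`, `identity_known`.
#' @param expected Optional named list of externally stated values (e.g.
#'   `list(total_genes = 410, distinct_identities = 17)`); computed values
#'   are always reported, with a `discrepancies` tibble flagging differences.
#' @return A `cohort_summary` list: `total_genes`, `n_genomes`,
#'   `distinct_identities`, `distinct_amino_acids`, `per_genome_totals`,
#'   `identity_incidence` (genomes carrying each identity),
#'   `strand_uniform` (per-genome flag, NA when strand unknown),
#'   `discrepancies`.
#' @export
summary_stats <- function(inventory_long, expected = NULL) {
  d <- inventory_long
  n_genomes <- length(unique(d$genome))
  known <- if ("identity_known" %in% names(d)) {
    d[d$identity_known %in% TRUE, , drop = FALSE]
  } else {
    d[!is.na(d$codon), , drop = FALSE]
  }
  key <- identity_key(known$amino_acid, known$codon)
  incidence <- vapply(split(known$genome, key),
                      function(g) length(unique(g)), integer(1))
  incidence <- tibble(identity = names(incidence),
                      n_genomes = unname(incidence))
  incidence <- incidence[order(-incidence$n_genomes, incidence$identity), ]
  strand_uniform <- if ("strand" %in% names(d)) {
    vapply(split(d$strand, d$genome),
           function(s) length(unique(s)) == 1, logical(1))
  } else {
    setNames(rep(NA, n_genomes), unique(d$genome))
  }
  res <- list(
    total_genes = nrow(d),
    n_genomes = n_genomes,
    distinct_identities = length(unique(key)),
    distinct_amino_acids = length(unique(known$amino_acid)),
    per_genome_totals = vapply(split(d, d$genome), nrow, integer(1)),
    identity_incidence = incidence,
    strand_uniform = strand_uniform,
    discrepancies = tibble(quantity = character(), computed = numeric(),
                           expected = numeric()))
  if (!is.null(expected)) {
    for (q in names(expected)) {
      comp <- res[[q]]
      if (!is.null(comp) && length(comp) == 1 && comp != expected[[q]]) {
        res$discrepancies <- bind_rows(
          res$discrepancies,
          tibble(quantity = q, computed = as.numeric(comp),
                 expected = as.numeric(expected[[q]])))
      }
    }
  }
  structure(res, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> %d genomes, %d tRNA genes, %d identities, %d amino acids\n",
    x$n_genomes, x$total_genes, x$distinct_identities,
    x$distinct_amino_acids))
  if (nrow(x$discrepancies)) {
    cat("  discrepancies vs stated values:\n")
    print(as.data.frame(x$discrepancies))
  }
  invisible(x)
}
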