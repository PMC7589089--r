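# tRNA gene cluster detection. Survey definition ("no intervening genes;
# 2 or more") is strict mode; relaxed mode admits bounded gaps and a few
# intervening non-tRNA features, which is how interrupted chlorovirus
# clusters (spacers up to ~1.4 kb containing a CDS) stay single clusters
# while the ~30 kb orphan tRNA never joins.

#' Cluster detection parameters
#'
#' @param mode `"strict"` (no intervening non-tRNA features) or `"relaxed"`.
#' @param max_gap_nt Maximum intergenic spacer to chain across (relaxed
#'   default 2000 nt keeps every published intra-cluster spacer, including
#'   1416 nt, while a 29-36 kb orphan never joins).
#' @param max_intervening_features Relaxed mode: maximum non-tRNA features
#'   allowed inside one junction gap.
#' @param min_genes Minimum genes to emit a cluster (>= 2 by the survey
#'   definition).
#' @param require_same_strand Break the chain on a strand switch?
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(mode = c("relaxed", "strict"), max_gap_nt = 2000,
                           max_intervening_features = 3, min_genes = 2,
                           require_same_strand = TRUE) {
  mode <- match.arg(mode)
  if (min_genes < 2) stop("min_genes must be >= 2 (cluster definition)")
  structure(list(mode = mode, max_gap_nt = as.integer(max_gap_nt),
                 max_intervening_features = as.integer(max_intervening_features),
                 min_genes = as.integer(min_genes),
                 require_same_strand = isTRUE(require_same_strand)),
            class = "cluster_params")
}

#' Intergenic spacer between two adjacent genes
#'
#' The number of nucleotides strictly between two genes:
#' `start(next) - end(prev) - 1`. Abutting genes have spacer 0; overlap is an
#' annotation conflict and errors.
#'
#' @param prev,next_ One-row inventory/feature tibbles (or lists) with
#'   `start` and `end` on the same genome.
#' @return Integer spacer length.
#' @export
intergenic_spacer <- function(prev, next_) {
  pe <- if (is.data.frame(prev)) prev$end[[1]] else prev$end
  ns <- if (is.data.frame(next_)) next_$start[[1]] else next_$start
  if (ns <= pe) {
    stop("annotation conflict: overlapping tRNA genes (end ", pe,
         " >= start ", ns, ")")
  }
  as.integer(ns - pe - 1L)
}

# non-tRNA features whose span intersects the open gap (prev_end, next_start)
intervening_features <- function(all_features, prev_end, next_start) {
  if (is.null(all_features) || nrow(all_features) == 0) {
    return(feature_table())
  }
  f <- all_features[all_features$kind != "tRNA", , drop = FALSE]
  f[f$end > prev_end & f$start < next_start, , drop = FALSE]
}

#' Detect tRNA gene clusters and orphans
#'
#' Greedy left-to-right chaining over the genome-ordered inventory: the chain
#' extends across a junction when the spacer is at most `max_gap_nt`, the
#' strand constraint holds, and the junction's intervening non-tRNA features
#' are admissible (strict: none; relaxed: at most
#' `max_intervening_features`). Chains with at least `min_genes` genes become
#' clusters; the remaining tRNAs are orphans, each with the distance to its
#' nearest cluster boundary.
#'
#' @param inventory Genome-ordered tibble from [build_inventory()] (or any
#'   tibble with `start`, `end`, `strand` and identity columns).
#' @param all_features Feature tibble of the genome (for interruption logic);
#'   `NULL` means no non-tRNA features are known.
#' @param params A [cluster_params()].
#' @param genome_length Optional, enables genome-third classification.
#' @return List with `clusters` (list of `trna_cluster` objects) and
#'   `orphans` (tibble with `nearest_cluster` and `distance_nt`).
#' @export
detect_clusters <- function(inventory, all_features = NULL,
                            params = cluster_params(),
                            genome_length = NULL) {
  n <- nrow(inventory)
  if (n == 0) {
    return(list(clusters = list(),
                orphans = cbind(inventory, nearest_cluster = integer(),
                                distance_nt = integer())))
  }
  inventory <- inventory[order(inventory$start, inventory$end), , drop = FALSE]

  chain_id <- integer(n)
  chain_id[1] <- 1L
  junction_interruptions <- vector("list", n)  # features inside junction i-1 -> i
  for (i in seq_len(n)[-1]) {
    gap <- intergenic_spacer(inventory[i - 1, ], inventory[i, ])
    iv <- intervening_features(all_features, inventory$end[i - 1],
                               inventory$start[i])
    strand_ok <- !params$require_same_strand ||
      inventory$strand[i] == inventory$strand[i - 1]
    iv_ok <- if (params$mode == "strict") {
      nrow(iv) == 0
    } else {
      nrow(iv) <= params$max_intervening_features
    }
    if (gap <= params$max_gap_nt && strand_ok && iv_ok) {
      chain_id[i] <- chain_id[i - 1]
      junction_interruptions[[i]] <- iv
    } else {
      chain_id[i] <- chain_id[i - 1] + 1L
    }
  }

  clusters <- list()
  orphan_idx <- integer()
  for (cid in unique(chain_id)) {
    idx <- which(chain_id == cid)
    if (length(idx) < params$min_genes) {
      orphan_idx <- c(orphan_idx, idx)
      next
    }
    genes <- inventory[idx, , drop = FALSE]
    spacers <- if (length(idx) > 1) {
      vapply(seq_along(idx)[-1], function(j) {
        intergenic_spacer(genes[j - 1, ], genes[j, ])
      }, integer(1))
    } else {
      integer()
    }
    interrupting <- bind_rows(junction_interruptions[idx])
    strands <- unique(genes$strand)
    cl <- structure(list(
      genes = genes, spacers = spacers, interrupting_features = interrupting,
      span = c(start = min(genes$start), end = max(genes$end)),
      strand = if (length(strands) == 1) strands else "mixed",
      n_genes = length(idx)), class = "trna_cluster")
    if (!is.null(genome_length)) {
      cl$genome_third <- genome_third(cl, genome_length)
    }
    clusters[[length(clusters) + 1]] <- cl
  }

  orphans <- inventory[orphan_idx, , drop = FALSE]
  orphans$nearest_cluster <- NA_integer_
  orphans$distance_nt <- NA_integer_
  if (nrow(orphans) && length(clusters)) {
    for (k in seq_len(nrow(orphans))) {
      d <- vapply(clusters, function(cl) {
        if (orphans$start[k] > cl$span[["end"]]) {
          orphans$start[k] - cl$span[["end"]] - 1
        } else if (orphans$end[k] < cl$span[["start"]]) {
          cl$span[["start"]] - orphans$end[k] - 1
        } else {
          0
        }
      }, numeric(1))
      orphans$nearest_cluster[k] <- which.min(d)
      orphans$distance_nt[k] <- as.integer(min(d))
    }
  }
  list(clusters = clusters, orphans = orphans)
}

#' Genome-third position of a cluster
#'
#' Classifies the cluster midpoint against thirds of the genome; a midpoint
#' exactly on a boundary falls in the earlier third (closed-left convention).
#'
#' @param cluster A `trna_cluster`.
#' @param genome_length Genome length in nt.
#' @return `"first"`, `"middle"` or `"last"`.
#' @export
genome_third <- function(cluster, genome_length) {
  mid <- mean(cluster$span)
  if (mid <= genome_length / 3) "first"
  else if (mid <= 2 * genome_length / 3) "middle"
  else "last"
}

#' Could a cluster be co-transcribed as one transcript?
#'
#' True iff all genes are on one strand, every spacer is at most
#' `max_spacer` and no non-tRNA feature interrupts the cluster — the
#' configuration under which a tRNA cluster is plausibly transcribed as a
#' single precursor and processed into individual tRNAs.
#'
#' @param cluster A `trna_cluster`.
#' @param max_spacer Maximum spacer compatible with co-transcription.
#' @return Logical flag.
#' @export
cotranscription_candidate <- function(cluster, max_spacer = 500) {
  cluster$strand != "mixed" &&
    all(cluster$spacers <= max_spacer) &&
    nrow(cluster$interrupting_features) == 0
}

#' @export
print.trna_cluster <- function(x, ...) {
  lab <- ifelse(is.na(x$genes$amino_acid), "?",
                paste0(x$genes$amino_acid, "(", x$genes$codon, ")"))
  cat(sprintf("<trna_cluster> %d genes, span %d..%d, strand %s\n",
              x$n_genes, x$span["start"], x$span["end"], x$strand))
  cat("  ", paste(lab, collapse = " - "), "\n")
  if (length(x$spacers)) {
    cat("  spacers:", paste(x$spacers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabular cluster report over a set of genomes
#'
#' One row per genome: gene order with interleaved spacers (the layout of the
#' published per-clade tables), total tRNA count, cluster and orphan counts.
#' The per-clade union of identities is attached as attribute
#' `clade_identities`.
#'
#' @param genomes List of [genome_record()] objects.
#' @param params A [cluster_params()].
#' @return A tibble, one row per genome.
#' @export
cluster_table <- function(genomes, params = cluster_params()) {
  if (!length(genomes)) {
    return(tibble(genome = character(), clade = character(),
                  total_trnas = integer(), n_clusters = integer(),
                  n_orphans = integer(), order = character()))
  }
  rows <- lapply(genomes, function(rec) {
    inv <- build_inventory(rec)
    det <- detect_clusters(inv, rec$features, params, rec$length)
    order_str <- paste(vapply(det$clusters, function(cl) {
      lab <- paste0(cl$genes$amino_acid, "(", cl$genes$codon, ")")
      if (length(cl$spacers)) {
        paste(c(rbind(head(lab, -1), cl$spacers), tail(lab, 1)),
              collapse = "-")
      } else {
        lab
      }
    }, character(1)), collapse = " | ")
    tibble(genome = rec$id, clade = rec$clade, total_trnas = nrow(inv),
           n_clusters = length(det$clusters), n_orphans = nrow(det$orphans),
           order = order_str)
  })
  out <- bind_rows(rows)
  invs <- lapply(genomes, build_inventory)
  long <- bind_rows(invs)
  attr(out, "clade_identities") <- if (nrow(long)) {
    known <- long[long$identity_known, , drop = FALSE]
    lapply(split(known, known$clade), function(d) {
      sort(unique(paste0(d$amino_acid, "-", d$codon)))
    })
  } else {
    list()
  }
  out
}
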