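# Deterministic synthetic genomes with fully known ground truth, emulating
# the statistical structure of the chlorovirus system: an AT-rich virus
# (~40% GC coding bias) carrying one tRNA gene cluster with short spacers,
# occasional interrupting CDSs, pseudogenes, a tRNA-Tyr intron 1 nt 3' of
# the anticodon, an optional orphan tRNA ~30 kb downstream, all tRNA genes
# on one strand; and a GC-rich host (~67% GC coding bias) without tRNA
# clusters. CDS codons are drawn i.i.d. from a configured codon table (the
# downstream analysis uses only marginal codon frequencies) and intergenic
# sequence is GC-matched to the genome target.

# 72 nt exonic tRNA scaffold: acceptor stem (1-7), Box A (8-18), D-arm
# filler (19-33), anticodon (34-36), filler (37-48), Box B (49-59),
# 3' end (60-72, no terminal CCA).
TRNA_SCAFFOLD_5P <- "GCGGATT"            # 1-7
TRNA_SCAFFOLD_DARM <- "CAGACTGAAGATCTG"  # 19-33
TRNA_SCAFFOLD_MID <- "AACCGGTTCAAA"      # 37-48
TRNA_SCAFFOLD_3P <- "TGGAGGTCGCGGA"      # 60-72 (ends GGA, not CCA)
TRNA_ANTICODON_START <- 34L

# Deterministic concrete instance of an IUPAC consensus (first member base).
iupac_instantiate <- function(consensus) {
  letters <- strsplit(toupper(dna(consensus)), "")[[1]]
  paste(vapply(letters, function(cl) {
    substr(Biostrings::IUPAC_CODE_MAP[[cl]], 1, 1)
  }, character(1)), collapse = "")
}

random_bases <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic tRNA gene sequence
#'
#' Builds a ~72 nt exonic tRNA gene on a fixed scaffold: anticodon at exonic
#' positions 34-36, concrete instances of the Box A and Box B promoter
#' consensus embedded at scaffold offsets 8 and 49 (A 5' of B), no terminal
#' CCA. An intron, when requested, is inserted starting `offset` exonic
#' nucleotides 3' of the anticodon (the chlorovirus tRNA-Tyr geometry is
#' offset 1, length 10-14). Pseudogenes keep their annotation but carry a
#' disrupted D-arm.
#'
#' @param amino_acid Three-letter amino-acid code consistent with the codon.
#' @param anticodon RNA triplet 5'->3'; the cognate codon is its reverse
#'   complement.
#' @param intron `NULL` or `list(offset =, length =)`.
#' @param boxes A [box_motif_config()] whose consensus to embed.
#' @param pseudogene Disrupt the D-arm filler?
#' @return List with `sequence` (unspliced, DNA), `exons` (relative
#'   coordinate data.frame or NULL), `anticodon_start` (unspliced position),
#'   `length`.
#' @export
generate_trna_gene_sequence <- function(amino_acid, anticodon, intron = NULL,
                                        boxes = box_motif_config(),
                                        pseudogene = FALSE) {
  codon <- anticodon_to_codon(anticodon)
  aa_of_codon <- codon_to_aa(codon, three_letter = TRUE)
  if (!identical(aa_of_codon, amino_acid)) {
    stop("anticodon ", anticodon, " reads ", codon, " (", aa_of_codon,
         "), inconsistent with amino acid ", amino_acid)
  }
  darm <- TRNA_SCAFFOLD_DARM
  if (pseudogene) substr(darm, 7, 10) <- "TTTT"  # anticodon-arm disruption
  exonic <- paste0(TRNA_SCAFFOLD_5P,
                   iupac_instantiate(boxes$box_a_consensus),
                   darm,
                   toupper(dna(anticodon)),
                   TRNA_SCAFFOLD_MID,
                   iupac_instantiate(boxes$box_b_consensus),
                   TRNA_SCAFFOLD_3P)
  stopifnot(nchar(exonic) == 72)
  if (is.null(intron)) {
    return(list(sequence = exonic, exons = NULL,
                anticodon_start = TRNA_ANTICODON_START, length = 72L))
  }
  stopifnot(intron$offset >= 0, intron$length >= 1)
  cut <- TRNA_ANTICODON_START + 2L + intron$offset  # last exonic nt before intron
  intron_seq <- random_bases(intron$length, gc = 0.4)
  seq <- paste0(substr(exonic, 1, cut), intron_seq,
                substr(exonic, cut + 1, 72))
  list(sequence = seq,
       exons = data.frame(start = c(1L, cut + intron$length + 1L),
                          end = c(cut, 72L + intron$length)),
       anticodon_start = TRNA_ANTICODON_START,
       length = 72L + as.integer(intron$length))
}

#' Specify a synthetic tRNA cluster
#'
#' @param entries Tibble/data.frame with one row per clustered gene:
#'   `amino_acid`, `anticodon` (RNA 5'->3'), optional `pseudogene`,
#'   `intron_offset`, `intron_length` (NA = no intron).
#' @param spacers Integer vector of intergenic spacers, length
#'   `nrow(entries) - 1`, each >= 0.
#' @param interruptions Optional tibble `junction` (spacer index whose gap
#'   holds a CDS), `cds_length` (< spacer at that junction).
#' @param strand `"+"` or `"-"` for every tRNA gene (the chlorovirus
#'   single-strand property).
#' @param cluster_start Genomic start of the first gene (NA = place at the
#'   genome's center).
#' @param orphans Optional tibble `amino_acid`, `anticodon`, `distance`
#'   (nt beyond the cluster 3' end; should exceed the relaxed `max_gap_nt`).
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(entries, spacers, interruptions = NULL,
                         strand = "+", cluster_start = NA,
                         orphans = NULL) {
  entries <- as_tibble(entries)
  for (col in c("pseudogene")) {
    if (!col %in% names(entries)) entries[[col]] <- FALSE
  }
  for (col in c("intron_offset", "intron_length")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_integer_
  }
  if (length(spacers) != max(nrow(entries) - 1, 0)) {
    stop("need exactly ", nrow(entries) - 1, " spacers")
  }
  if (any(spacers < 0)) stop("spacers must be >= 0")
  if (!is.null(interruptions)) {
    interruptions <- as_tibble(interruptions)
    bad <- interruptions$cds_length > spacers[interruptions$junction] - 2
    if (any(bad)) stop("interrupting CDS longer than its junction gap")
  }
  structure(list(entries = entries, spacers = as.integer(spacers),
                 interruptions = interruptions, strand = strand,
                 cluster_start = if (is.na(cluster_start)) NA else
                   as.integer(cluster_start),
                 orphans = orphans),
            class = "cluster_spec")
}

#' Simulation configuration for one synthetic genome
#'
#' @param seed Integer; fully determines the output.
#' @param genome_length Total length in nt.
#' @param cds_count Number of background CDSs.
#' @param cds_codons Mean codon count per CDS (lengths are drawn uniformly
#'   within +/- 20%).
#' @param codon_table Named numeric vector codon (RNA) -> percent frequency
#'   over the 61 sense codons, e.g. a column of the published codon-usage
#'   table; drives both coding composition and (approximately) coding GC.
#' @param intergenic_gc Target GC fraction of intergenic sequence.
#' @param cluster A [cluster_spec()] or `NULL` (host genomes).
#' @param clade Clade label for the emitted record.
#' @param id Genome id.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(seed, genome_length = 60000, cds_count = 25,
                              cds_codons = 300, codon_table,
                              intergenic_gc = NULL, cluster = NULL,
                              clade = "other", id = NULL) {
  missing_cd <- setdiff(sense_codons(), names(codon_table))
  if (length(missing_cd)) {
    stop("codon_table missing codons: ", paste(missing_cd, collapse = ", "))
  }
  s <- sum(codon_table[sense_codons()])
  if (abs(s - 100) > 5) stop("codon_table must sum to ~100, got ", round(s, 2))
  if (is.null(intergenic_gc)) {
    gcw <- vapply(strsplit(sense_codons(), ""), function(x) {
      sum(x %in% c("G", "C")) / 3
    }, numeric(1))
    intergenic_gc <- sum(gcw * codon_table[sense_codons()]) / s
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 cds_count = as.integer(cds_count),
                 cds_codons = as.integer(cds_codons),
                 codon_table = codon_table[sense_codons()] / s * 100,
                 intergenic_gc = intergenic_gc, cluster = cluster,
                 clade = clade,
                 id = id %||% sprintf("synth%06d", as.integer(seed))),
            class = "genome_sim_config")
}

sample_cds <- function(n_codons, codon_table) {
  codons <- sample(names(codon_table), n_codons, replace = TRUE,
                   prob = codon_table)
  paste0(paste(dna(codons), collapse = ""), "TAA")
}

#' Generate a synthetic virus genome with a tRNA cluster
#'
#' Lays out background CDSs (codons i.i.d. from the configured table) around
#' a tRNA cluster built from the [cluster_spec()], with GC-matched intergenic
#' sequence; all tRNA genes are on one strand. Deterministic per seed. The
#' returned truth record holds exact coordinates, identities, spacers,
#' intron geometries, pseudogene flags, cluster membership and orphan
#' distances for every emitted tRNA gene.
#'
#' @param config A [genome_sim_config()] with a non-NULL `cluster`
#'   (use [generate_host_genome()] for cluster-free genomes).
#' @param boxes A [box_motif_config()] embedded in each tRNA gene.
#' @return List with `record` ([genome_record()]) and `truth` (list with
#'   `genes` tibble, `spacers`, `cluster_span`, `orphan` tibble).
#' @export
generate_virus_genome <- function(config, boxes = box_motif_config()) {
  if (is.null(config$cluster)) stop("virus config requires a cluster_spec")
  with_local_seed(config$seed, generate_genome_impl(config, boxes))
}

#' Generate a synthetic host genome (no tRNA cluster)
#'
#' @param config A [genome_sim_config()] with `cluster = NULL` and
#'   `cds_count >= 1`.
#' @return As [generate_virus_genome()]; the truth gene table is empty.
#' @export
generate_host_genome <- function(config) {
  if (!is.null(config$cluster)) stop("host config must not carry a cluster")
  if (config$cds_count < 1) stop("host genome requires at least one CDS")
  with_local_seed(config$seed, generate_genome_impl(config, NULL))
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

generate_genome_impl <- function(config, boxes) {
  L <- config$genome_length
  spec <- config$cluster

  # 1. build the tRNA cluster block (sequence + relative features)
  cluster_block <- NULL
  if (!is.null(spec)) {
    cluster_block <- build_cluster_block(spec, boxes, config)
    if (is.na(spec$cluster_start)) {
      spec$cluster_start <- max(1L, as.integer(L / 2 - cluster_block$width / 2))
    }
    reserve_end <- spec$cluster_start + cluster_block$width - 1L
    if (spec$cluster_start < 1 || reserve_end > L) {
      stop("cluster (plus orphans) does not fit in the genome")
    }
  }

  # 2. background sequence, GC-matched
  seq <- random_bases(L, gc = config$intergenic_gc)

  features <- list()
  truth_genes <- list()

  # 3. stamp the cluster and orphans
  if (!is.null(cluster_block)) {
    seq <- paste0(substr(seq, 1, spec$cluster_start - 1),
                  cluster_block$sequence,
                  substr(seq, spec$cluster_start + cluster_block$width, L))
    stopifnot(nchar(seq) == L)
    off <- spec$cluster_start - 1L
    for (f in cluster_block$features) {
      f$start <- f$start + off
      f$end <- f$end + off
      if (!is.null(f$exons)) {
        f$exons$start <- f$exons$start + off
        f$exons$end <- f$exons$end + off
      }
      features[[length(features) + 1]] <- f
    }
    tg <- cluster_block$truth
    tg$start <- tg$start + off
    tg$end <- tg$end + off
    cluster_span <- c(start = min(tg$start[tg$in_cluster]),
                      end = max(tg$end[tg$in_cluster]))
    truth <- list(genes = tg, spacers = cluster_block$spacers,
                  cluster_span = cluster_span,
                  orphan = tg[!tg$in_cluster, , drop = FALSE])
  } else {
    truth <- list(genes = empty_truth_genes(), spacers = integer(),
                  cluster_span = NULL, orphan = empty_truth_genes())
  }

  # 4. place background CDSs outside the reserved cluster+orphan region
  occupied <- lapply(features, function(f) c(f$start, f$end))
  if (!is.null(cluster_block)) {
    occupied[[length(occupied) + 1]] <- c(spec$cluster_start,
                                          spec$cluster_start +
                                            cluster_block$width - 1L)
    orph <- truth$orphan
    if (nrow(orph)) {
      for (k in seq_len(nrow(orph))) {
        occupied[[length(occupied) + 1]] <- c(orph$start[k], orph$end[k])
      }
    }
  }
  cds_lengths <- 3L * as.integer(round(stats::runif(
    config$cds_count, 0.8 * config$cds_codons, 1.2 * config$cds_codons))) + 3L
  for (k in seq_len(config$cds_count)) {
    pos <- find_free_slot(L, cds_lengths[k], occupied)
    if (is.na(pos)) next  # genome too crowded; skip silently, truth unaffected
    cds_seq <- sample_cds((cds_lengths[k] - 6L) %/% 3L, config$codon_table)
    seq <- paste0(substr(seq, 1, pos - 1), cds_seq,
                  substr(seq, pos + nchar(cds_seq), L))
    occupied[[length(occupied) + 1]] <- c(pos, pos + nchar(cds_seq) - 1L)
    features[[length(features) + 1]] <- list(
      feature_id = sprintf("cds%03d", k), kind = "CDS",
      start = pos, end = pos + nchar(cds_seq) - 1L, strand = "+",
      product = "hypothetical protein", anticodon = NA_character_,
      pseudo = FALSE, exons = NULL)
  }
  stopifnot(nchar(seq) == L)

  ft <- bind_rows(lapply(features, function(f) {
    tibble(feature_id = f$feature_id, kind = f$kind, start = f$start,
           end = f$end, strand = f$strand, product = f$product,
           anticodon = f$anticodon, pseudo = f$pseudo, exons = list(f$exons))
  }))
  if (!nrow(ft)) ft <- feature_table()
  rec <- genome_record(config$id, seq, ft, clade = config$clade)
  list(record = rec, truth = truth)
}

empty_truth_genes <- function() {
  tibble(gene = integer(), amino_acid = character(), codon = character(),
         anticodon = character(), start = integer(), end = integer(),
         strand = character(), pseudogene = logical(),
         intron_offset = integer(), intron_length = integer(),
         in_cluster = logical(), orphan_distance = integer())
}

# Lay the cluster genes (and orphans) onto a local coordinate system starting
# at 1; interruption CDSs are placed inside their junction gaps.
build_cluster_block <- function(spec, boxes, config) {
  n <- nrow(spec$entries)
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    e <- spec$entries[i, ]
    intron <- if (!is.na(e$intron_length)) {
      list(offset = e$intron_offset, length = e$intron_length)
    } else {
      NULL
    }
    genes[[i]] <- generate_trna_gene_sequence(
      e$amino_acid, e$anticodon, intron = intron, boxes = boxes,
      pseudogene = isTRUE(e$pseudogene))
  }
  seq_parts <- character()
  features <- list()
  truth <- list()
  pos <- 1L
  gene_starts <- integer(n)
  for (i in seq_len(n)) {
    g <- genes[[i]]
    e <- spec$entries[i, ]
    placed <- place_trna_gene(g, e, pos, spec$strand, sprintf("trna%03d", i))
    seq_parts <- c(seq_parts, placed$sequence)
    features[[length(features) + 1]] <- placed$feature
    truth[[length(truth) + 1]] <- placed$truth
    gene_starts[i] <- pos
    pos <- pos + g$length
    if (i < n) {
      gap <- spec$spacers[i]
      gap_seq <- random_bases(gap, gc = config$intergenic_gc)
      irow <- NULL
      if (!is.null(spec$interruptions)) {
        hit <- which(spec$interruptions$junction == i)
        if (length(hit)) irow <- spec$interruptions[hit[1], ]
      }
      if (!is.null(irow)) {
        cl <- as.integer(irow$cds_length)
        pad <- (gap - cl) %/% 2
        cds_seq <- sample_cds(max((cl - 3L) %/% 3L, 1L), config$codon_table)
        cl <- nchar(cds_seq)  # actual length: whole codons + stop, <= requested
        gap_seq <- paste0(substr(gap_seq, 1, pad), cds_seq,
                          substr(gap_seq, pad + cl + 1, gap))
        features[[length(features) + 1]] <- list(
          feature_id = sprintf("intcds%03d", i), kind = "CDS",
          start = pos + pad, end = pos + pad + cl - 1L, strand = "+",
          product = "hypothetical protein", anticodon = NA_character_,
          pseudo = FALSE, exons = NULL)
      }
      stopifnot(nchar(gap_seq) == gap)
      seq_parts <- c(seq_parts, gap_seq)
      pos <- pos + gap
    }
  }
  cluster_width <- pos - 1L  # end coordinate of the last clustered gene
  # orphans: distance nt beyond the 3' end of the cluster
  if (!is.null(spec$orphans) && nrow(spec$orphans)) {
    orph <- as_tibble(spec$orphans)
    last_end <- cluster_width
    total_extra <- 0L
    for (k in seq_len(nrow(orph))) {
      og <- generate_trna_gene_sequence(orph$amino_acid[k],
                                        orph$anticodon[k], boxes = boxes)
      gap <- as.integer(orph$distance[k]) - total_extra
      gap_seq <- random_bases(gap, gc = config$intergenic_gc)
      placed <- place_trna_gene(
        og, tibble(amino_acid = orph$amino_acid[k],
                   anticodon = orph$anticodon[k], pseudogene = FALSE,
                   intron_offset = NA_integer_, intron_length = NA_integer_),
        last_end + gap + 1L, spec$strand, sprintf("orph%03d", k))
      placed$truth$in_cluster <- FALSE
      placed$truth$orphan_distance <- as.integer(orph$distance[k])
      seq_parts <- c(seq_parts, gap_seq, placed$sequence)
      features[[length(features) + 1]] <- placed$feature
      truth[[length(truth) + 1]] <- placed$truth
      last_end <- last_end + gap + og$length
      total_extra <- total_extra + gap + og$length
    }
    cluster_width <- last_end
  }
  tg <- bind_rows(truth)
  tg$gene <- seq_len(nrow(tg))
  list(sequence = paste(seq_parts, collapse = ""),
       width = as.integer(cluster_width), features = features,
       truth = tg, spacers = spec$spacers)
}

place_trna_gene <- function(gene, entry, start, strand, feature_id) {
  len <- gene$length
  seq <- gene$sequence
  exons <- gene$exons
  codon <- anticodon_to_codon(entry$anticodon)
  if (strand == "-") {
    seq <- reverse_complement(seq)
    if (!is.null(exons)) {
      exons <- data.frame(start = len - exons$end + 1L,
                          end = len - exons$start + 1L)
      exons <- exons[order(exons$start), , drop = FALSE]
    }
  }
  abs_exons <- if (!is.null(exons)) {
    data.frame(start = exons$start + start - 1L, end = exons$end + start - 1L)
  } else {
    NULL
  }
  feature <- list(
    feature_id = feature_id, kind = "tRNA", start = start,
    end = start + len - 1L, strand = strand,
    product = sprintf("tRNA-%s", entry$amino_acid),
    anticodon = toupper(dna(entry$anticodon)),
    pseudo = isTRUE(entry$pseudogene), exons = abs_exons)
  truth <- tibble(
    gene = NA_integer_, amino_acid = entry$amino_acid, codon = codon,
    anticodon = entry$anticodon, start = as.integer(start),
    end = as.integer(start + len - 1L), strand = strand,
    pseudogene = isTRUE(entry$pseudogene),
    intron_offset = entry$intron_offset %||% NA_integer_,
    intron_length = entry$intron_length %||% NA_integer_,
    in_cluster = TRUE, orphan_distance = NA_integer_)
  list(sequence = seq, feature = feature, truth = truth)
}

find_free_slot <- function(L, width, occupied, margin = 30L, tries = 200L) {
  for (t in seq_len(tries)) {
    s <- as.integer(stats::runif(1, 1, L - width - margin))
    e <- s + width - 1L
    clash <- any(vapply(occupied, function(o) {
      s <= o[2] + margin && e >= o[1] - margin
    }, logical(1)))
    if (!clash) return(s)
  }
  NA_integer_
}

#' Write a generated genome as GenBank, GFF3, FASTA and truth JSON
#'
#' @param generated Output of [generate_virus_genome()] or
#'   [generate_host_genome()].
#' @param dir Output directory (created if needed).
#' @param basename File stem; defaults to the record id.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_genome_files <- function(generated, dir, basename = NULL) {
  rec <- generated$record
  basename <- basename %||% rec$id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genbank = file.path(dir, paste0(basename, ".gbk")),
             gff3 = file.path(dir, paste0(basename, ".gff3")),
             fasta = file.path(dir, paste0(basename, ".fna")),
             truth = file.path(dir, paste0(basename, ".truth.json")))
  write_genbank(rec, paths["genbank"])
  write_gff3(rec, paths["gff3"], paths["fasta"])
  truth <- generated$truth
  json <- list(genes = truth$genes, spacers = truth$spacers,
               cluster_span = truth$cluster_span,
               orphan = truth$orphan)
  jsonlite::write_json(json, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(paths)
}
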