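# Shared fixtures and oracles for the test suite. Everything is built in
# code at test time; no binary fixtures.

uniform_codon_table <- function() {
  setNames(rep(100 / 61, 61), sense_codons())
}

codon_to_anticodon <- function(codon) {
  rna(reverse_complement(dna(codon)))
}

# Entries tibble for a cluster spec from a vector of cognate codons (RNA).
entries_from_codons <- function(codons, pseudogene = FALSE,
                                tyr_intron_length = 13L) {
  tibble::tibble(
    amino_acid = codon_to_aa(codons, three_letter = TRUE),
    anticodon = codon_to_anticodon(codons),
    pseudogene = rep_len(pseudogene, length(codons)),
    intron_offset = ifelse(codons == "UAC", 1L, NA_integer_),
    intron_length = ifelse(codons == "UAC", as.integer(tyr_intron_length),
                           NA_integer_))
}

# The 14-gene NC64A reference order (identity codons).
ma1e_codons <- function() {
  c("UUG", "AUA", "AAC", "UUA", "AGA", "AAC", "GGA", "AAC", "AAG", "CAG",
    "AAG", "UAC", "AAA", "AAG")
}

ma1e_spacers <- function() c(25, 23, 24, 3, 23, 3, 27, 3, 22, 23, 23, 30, 1)

# A small deterministic virus genome used across io/inventory/cluster tests.
make_test_virus <- function(seed = 42, codons = ma1e_codons(),
                            spacers = ma1e_spacers(), genome_length = 40000,
                            ...) {
  spec <- cluster_spec(entries_from_codons(codons), spacers = spacers, ...)
  cfg <- genome_sim_config(seed = seed, genome_length = genome_length,
                           cds_count = 8, cds_codons = 150,
                           codon_table = uniform_codon_table(),
                           cluster = spec, clade = "NC64A",
                           id = sprintf("testvirus%d", seed))
  generate_virus_genome(cfg)
}

# Random cluster configuration for property-style round trips. Draws gene
# count, identities, spacers (1-30 nt, occasionally one large interrupted
# gap), an optional pseudogene, a tRNA-Tyr intron when Tyr is drawn, and an
# optional ~30 kb orphan.
random_cluster_case <- function(seed) {
  withr::with_seed(seed + 1000L, {
    pool <- c("UUG", "AUA", "AAC", "UUA", "AGA", "GGA", "AAG", "CAG", "UAC",
              "AAA", "GAC", "GUU", "AGU", "AUU", "AUG", "ACU", "UUC", "ACG")
    n <- sample(3:14, 1)
    codons <- sample(pool, n, replace = TRUE)
    entries <- entries_from_codons(codons)
    if (stats::runif(1) < 0.3) {
      entries$pseudogene[sample(n, 1)] <- TRUE
    }
    spacers <- sample(1:30, n - 1, replace = TRUE)
    interruptions <- NULL
    if (n > 3 && stats::runif(1) < 0.4) {
      j <- sample(seq_len(n - 1), 1)
      spacers[j] <- sample(600:1500, 1)
      interruptions <- tibble::tibble(junction = j,
                                      cds_length = spacers[j] - 100L)
    }
    has_orphan <- stats::runif(1) < 0.3
    orphans <- if (has_orphan) {
      tibble::tibble(amino_acid = "Thr", anticodon = "AGU",
                     distance = sample(25000:31000, 1))
    } else {
      NULL
    }
    spec <- cluster_spec(entries, spacers = spacers,
                         interruptions = interruptions,
                         cluster_start = 1000L, orphans = orphans)
    genome_length <- if (has_orphan) 36000L else 8000L
    genome_sim_config(seed = seed, genome_length = genome_length,
                      cds_count = 3, cds_codons = 80,
                      codon_table = uniform_codon_table(), cluster = spec,
                      id = sprintf("case%04d", seed))
  })
}

# Exponential-time LCS oracle: longest common subsequence by exhaustive
# enumeration of subsequences of the shorter vector.
brute_force_lcs <- function(a, b) {
  if (length(a) > length(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  is_subseq <- function(x, y) {
    if (!length(x)) return(TRUE)
    j <- 1
    for (v in y) {
      if (v == x[j]) {
        j <- j + 1
        if (j > length(x)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  n <- length(a)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    if (is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}
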