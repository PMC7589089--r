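# Presence/absence bookkeeping, clade shared/unique sets, gene-order
# similarity, marker concatenation, cohort summaries.

test_that("the 41-genome cohort reproduces the published clade bookkeeping", {
  cohort <- load_cluster_fixtures()
  pm <- presence_matrix(cohort)
  expect_equal(ncol(pm), 41)
  su <- clade_shared_unique(pm)
  expect_length(su$common_all_clades, 7)
  expect_setequal(su$common_all_clades,
                  c("Ile-AUA", "Leu-UUA", "Asn-AAC", "Gly-GGA", "Lys-AAG",
                    "Tyr-UAC", "Arg-AGA"))
  expect_equal(unname(su$unique_gene_counts[c("NC64A", "Pbi", "SAG")]),
               c(2L, 3L, 4L))
  expect_setequal(su$unique_per_clade$NC64A, c("Gln-CAG", "Lys-AAA"))
  expect_setequal(su$unique_per_clade$SAG,
                  c("Ser-AGU", "Ile-AUU", "Met-AUG", "Thr-ACU"))
  expect_setequal(su$unique_per_clade$Pbi, c("Phe-UUC", "Thr-ACG"))
  expect_setequal(su$shared_pairs[["NC64A:SAG"]],
                  c("Asp-GAC", "Val-GUU", "Leu-UUG"))
  expect_length(su$shared_pairs[["NC64A:Pbi"]], 0)
  expect_length(su$shared_pairs[["Pbi:SAG"]], 0)
  # agreement with the printed cross-clade table
  t4 <- load_fixture("table4_presence")
  expect_equal(sum(t4$nc64a == "c"), length(su$common_all_clades))
  expect_equal(sum(t4$nc64a == "u"), unname(su$unique_gene_counts["NC64A"]))
  expect_equal(sum(t4$sag == "u"), unname(su$unique_gene_counts["SAG"]))
  expect_equal(sum(t4$pbi == "u"), unname(su$unique_gene_counts["Pbi"]))
})

test_that("degenerate presence matrices behave", {
  one <- tibble::tibble(genome = "v1", clade = "NC64A", amino_acid = "Asn",
                        codon = "AAC", identity_known = TRUE)
  pm <- presence_matrix(one)
  expect_equal(dim(pm), c(1L, 1L))
  expect_true(pm[1, 1])
  expect_warning(clade_shared_unique(pm), "fewer than two")
  su <- suppressWarnings(clade_shared_unique(pm))
  expect_length(su$common_all_clades, 0)
  expect_identical(su$unique_per_clade$NC64A, "Asn-AAC")
  # empty inventory -> all-absent column
  two <- dplyr::bind_rows(one,
                          tibble::tibble(genome = "v2", clade = "SAG",
                                         amino_acid = NA_character_,
                                         codon = NA_character_,
                                         identity_known = FALSE))
  pm2 <- presence_matrix(two)
  expect_false(any(pm2[, "v2"]))
})

test_that("pseudogene handling in presence is configurable", {
  inv <- tibble::tibble(genome = c("a", "a"), clade = c("X", "X"),
                        amino_acid = c("Asn", "Gly"),
                        codon = c("AAC", "GGA"),
                        pseudogene = c(FALSE, TRUE), identity_known = TRUE)
  with_pseudo <- presence_matrix(inv)
  expect_true(with_pseudo["Gly-GGA", "a"])
  without <- presence_matrix(inv, include_pseudogenes = FALSE)
  expect_false("Gly-GGA" %in% rownames(without))
})

test_that("gene-order similarity equals a brute-force LCS oracle", {
  cohort <- load_cluster_fixtures()
  ord <- function(v) cohort$codon[cohort$virus == v]
  pairs <- list(c("MA-1E", "Fr5L"), c("MA-1E", "Can0610SP"),
                c("Fr5L", "NTS-1"), c("NE-JV-1", "OR0704.2.2"))
  for (p in pairs) {
    a <- ord(p[1])
    b <- ord(p[2])
    expected <- 2 * brute_force_lcs(a, b) / (length(a) + length(b))
    expect_equal(gene_order_similarity(a, b), expected)
    expect_equal(gene_order_similarity(b, a),
                 gene_order_similarity(a, b))  # symmetric
  }
  expect_equal(gene_order_similarity(ord("MA-1E"), ord("MA-1E")), 1)
  expect_equal(gene_order_similarity(c("A", "B"), c("C", "D")), 0)
  expect_equal(gene_order_similarity(character(), character()), 1)
})

test_that("marker concatenation skips genomes missing a marker", {
  full <- make_test_virus(seed = 161,
                          codons = c("GGA", "UAC", "AGA", "AAC"),
                          spacers = c(5, 8, 4), genome_length = 4000)
  missing_gly <- make_test_virus(seed = 162, codons = c("UAC", "AGA", "AAC"),
                                 spacers = c(8, 4), genome_length = 4000)
  dup_arg <- make_test_virus(seed = 163,
                             codons = c("GGA", "UAC", "AGA", "AGA"),
                             spacers = c(5, 8, 4), genome_length = 4000)
  recs <- list(full$record, missing_gly$record, dup_arg$record)
  recs[[2]]$id <- "missingGly"
  recs[[3]]$id <- "dupArg"
  warns <- character()
  out <- withCallingHandlers(
    concatenate_markers(recs, c("GGA", "UAC", "AGA")),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("lacks marker", warns)))
  expect_true(any(grepl("copies", warns)))
  expect_setequal(names(out), c("testvirus161", "dupArg"))
  # concatenation is the spliced marker sequences in order
  inv <- build_inventory(full$record)
  expected <- paste0(inv$sequence[inv$codon == "GGA"],
                     inv$sequence[inv$codon == "UAC"],
                     inv$sequence[inv$codon == "AGA"])
  expect_equal(as.character(out[["testvirus161"]]), expected)
  expect_error(concatenate_markers(recs, character()), "empty")
})

test_that("cohort summary counts match the printed per-clade tables", {
  cohort <- load_cluster_fixtures()
  ss <- summary_stats(cohort, expected = list(total_genes = 410,
                                              distinct_identities = 17))
  expect_equal(ss$total_genes, 407)        # sum of the printed totals
  expect_equal(ss$n_genomes, 41)
  expect_equal(ss$distinct_identities, 18) # union of the table headings
  expect_equal(ss$distinct_amino_acids, 14)
  inc <- setNames(ss$identity_incidence$n_genomes,
                  ss$identity_incidence$identity)
  expect_equal(unname(inc["Arg-AGA"]), 41L)
  expect_equal(unname(inc["Gly-GGA"]), 39L)
  # the stated-vs-computed conflicts are surfaced, not hidden
  expect_setequal(ss$discrepancies$quantity,
                  c("total_genes", "distinct_identities"))
  # permutation invariance
  perm <- withr::with_seed(5, cohort[sample(nrow(cohort)), ])
  ss2 <- summary_stats(perm)
  expect_equal(ss2$total_genes, ss$total_genes)
  expect_equal(ss2$distinct_identities, ss$distinct_identities)
  expect_equal(sort(ss2$per_genome_totals), sort(ss$per_genome_totals))
})

test_that("strand uniformity is reported per genome", {
  inv <- tibble::tibble(genome = c("a", "a", "b", "b"),
                        clade = "X",
                        amino_acid = "Asn", codon = "AAC",
                        strand = c("+", "+", "+", "-"),
                        identity_known = TRUE)
  ss <- summary_stats(inv)
  expect_true(ss$strand_uniform[["a"]])
  expect_false(ss$strand_uniform[["b"]])
})
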