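# Spacer arithmetic, cluster chaining under strict/relaxed rules, orphans,
# genome-third classification, co-transcription heuristic.

test_that("intergenic spacer is start(next) - end(prev) - 1", {
  a <- tibble::tibble(start = 900, end = 1000)
  b <- tibble::tibble(start = 1026, end = 1100)
  expect_equal(intergenic_spacer(a, b), 25L)   # the reference Leu->Ile gap
  expect_equal(intergenic_spacer(tibble::tibble(start = 1, end = 1000),
                                 tibble::tibble(start = 1001, end = 1100)),
               0L)
  expect_error(intergenic_spacer(a, tibble::tibble(start = 999, end = 1100)),
               "annotation conflict")
})

test_that("an interrupted three-gene cluster stays whole under relaxed rules", {
  # gaps 132 and 1416 nt, the large one containing a CDS
  spec <- cluster_spec(entries_from_codons(c("AUA", "AGA", "AAC")),
                       spacers = c(132, 1416),
                       interruptions = tibble::tibble(junction = 2,
                                                      cds_length = 900),
                       cluster_start = 28000)
  cfg <- genome_sim_config(seed = 7, genome_length = 40000, cds_count = 5,
                           cds_codons = 100,
                           codon_table = uniform_codon_table(),
                           cluster = spec, clade = "Pbi", id = "pbilike")
  gen <- generate_virus_genome(cfg)
  inv <- build_inventory(gen$record)
  det <- detect_clusters(inv, gen$record$features, cluster_params(),
                         gen$record$length)
  expect_length(det$clusters, 1)
  expect_equal(det$clusters[[1]]$n_genes, 3)
  expect_equal(det$clusters[[1]]$spacers, c(132L, 1416L))
  expect_false(cotranscription_candidate(det$clusters[[1]]))
  expect_equal(det$clusters[[1]]$genome_third, "last")
  # strict mode splits at the interrupted junction; the trailing singleton
  # is not a cluster (min_genes = 2) and becomes an orphan
  dets <- detect_clusters(inv, gen$record$features,
                          cluster_params(mode = "strict"))
  expect_length(dets$clusters, 1)
  expect_equal(dets$clusters[[1]]$n_genes, 2)
  expect_equal(nrow(dets$orphans), 1)
})

test_that("a ~30 kb downstream tRNA is an orphan, never merged", {
  spec <- cluster_spec(
    entries_from_codons(c("AGU", "AGA", "AAC", "GGA", "UAC", "AAG")),
    spacers = c(4, 25, 22, 21, 4), cluster_start = 1500,
    orphans = tibble::tibble(amino_acid = "Thr", anticodon = "AGU",
                             distance = 30000))
  cfg <- genome_sim_config(seed = 8, genome_length = 36000, cds_count = 5,
                           cds_codons = 100,
                           codon_table = uniform_codon_table(),
                           cluster = spec, clade = "SAG", id = "saglike")
  gen <- generate_virus_genome(cfg)
  inv <- build_inventory(gen$record)
  det <- detect_clusters(inv, gen$record$features, cluster_params(),
                         gen$record$length)
  expect_length(det$clusters, 1)
  expect_equal(det$clusters[[1]]$n_genes, 6)
  expect_equal(det$clusters[[1]]$genome_third, "first")
  expect_equal(nrow(det$orphans), 1)
  expect_equal(det$orphans$amino_acid, "Thr")
  expect_equal(det$orphans$distance_nt, 30000L)
  expect_equal(det$orphans$nearest_cluster, 1L)
  expect_true(cotranscription_candidate(det$clusters[[1]]))
})

test_that("strict mode requires an empty junction; two tRNAs split by a CDS", {
  ft <- feature_table(
    feature_id = c("t1", "c1", "t2"), kind = c("tRNA", "CDS", "tRNA"),
    start = c(100, 180, 250), end = c(171, 230, 321),
    strand = "+", product = c("tRNA-Asn", "p", "tRNA-Arg"),
    anticodon = c("GTT", NA, "TCT"))
  rec <- genome_record("strictdemo", strrep("ACGT", 200), ft)
  inv <- build_inventory(rec)
  det <- detect_clusters(inv, rec$features, cluster_params(mode = "strict"))
  expect_length(det$clusters, 0)           # two singletons, min_genes = 2
  expect_equal(nrow(det$orphans), 2)
  detr <- detect_clusters(inv, rec$features, cluster_params())
  expect_length(detr$clusters, 1)          # relaxed admits the CDS
})

test_that("genome thirds use the midpoint with a closed-left boundary", {
  mk <- function(span) structure(list(span = c(start = span[1],
                                               end = span[2])),
                                 class = "trna_cluster")
  expect_equal(genome_third(mk(c(90, 110)), 1000), "first")    # mid 100
  expect_equal(genome_third(mk(c(490, 510)), 1000), "middle")  # mid 500
  expect_equal(genome_third(mk(c(900, 950)), 1000), "last")
  # midpoint exactly at length/3 stays in the first third
  expect_equal(genome_third(mk(c(333, 335)), 1002), "first")   # mid 334 = L/3
})

test_that("strand switches break clusters when required", {
  ft <- feature_table(
    feature_id = c("t1", "t2", "t3"), kind = "tRNA",
    start = c(100, 200, 300), end = c(171, 271, 371),
    strand = c("+", "+", "-"),
    product = "tRNA-Asn", anticodon = "GTT")
  rec <- genome_record("stranddemo", strrep("ACGT", 200), ft)
  inv <- build_inventory(rec)
  det <- detect_clusters(inv, rec$features, cluster_params())
  expect_length(det$clusters, 1)
  expect_equal(det$clusters[[1]]$n_genes, 2)
  det2 <- detect_clusters(inv, rec$features,
                          cluster_params(require_same_strand = FALSE))
  expect_equal(det2$clusters[[1]]$n_genes, 3)
  expect_equal(det2$clusters[[1]]$strand, "mixed")
  expect_false(cotranscription_candidate(det2$clusters[[1]]))
})

test_that("every tRNA lands in exactly one cluster or the orphan list", {
  for (seed in c(11, 12, 13, 14, 15)) {
    cfg <- random_cluster_case(seed)
    gen <- generate_virus_genome(cfg)
    inv <- build_inventory(gen$record)
    det <- detect_clusters(inv, gen$record$features, cluster_params())
    in_clusters <- sum(vapply(det$clusters, function(cl) cl$n_genes,
                              integer(1)))
    expect_equal(in_clusters + nrow(det$orphans), nrow(inv))
    ids <- c(unlist(lapply(det$clusters, function(cl) cl$genes$feature_id)),
             det$orphans$feature_id)
    expect_setequal(ids, inv$feature_id)
    expect_equal(anyDuplicated(ids), 0)
  }
})

test_that("enlarging max_gap_nt never increases the cluster count", {
  for (seed in c(21, 22, 23)) {
    cfg <- random_cluster_case(seed)
    gen <- generate_virus_genome(cfg)
    inv <- build_inventory(gen$record)
    gaps <- c(10, 50, 200, 1000, 2000, 40000)
    counts <- vapply(gaps, function(g) {
      length(detect_clusters(inv, gen$record$features,
                             cluster_params(max_gap_nt = g,
                                            max_intervening_features = 99)
                             )$clusters)
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cluster_table reports one row per genome with printed-style totals", {
  gens <- list(make_test_virus(seed = 131),
               make_test_virus(seed = 132, codons = c("AUA", "AGA", "AAC"),
                               spacers = c(132, 1416), genome_length = 8000))
  tab <- cluster_table(lapply(gens, `[[`, "record"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$total_trnas, c(14L, 3L))
  expect_match(tab$order[1], "^Leu\\(UUG\\)-25-Ile\\(AUA\\)")
  expect_equal(cluster_table(list())$genome, character(0))
  clades <- attr(tab, "clade_identities")
  expect_true("NC64A" %in% names(clades))
})
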