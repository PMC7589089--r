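# Codon usage tables, the virus/host ratio statistic, favorability.

test_that("codon counting drops the terminal stop and tracks QC", {
  t1 <- codon_frequencies("ATGAAAAAATAA")
  f <- setNames(t1$freq, t1$codon)
  expect_equal(unname(f["AUG"]), 100 / 3)
  expect_equal(unname(f["AAA"]), 200 / 3)
  expect_equal(attr(t1, "total_codons"), 3L)
  # all 61 sense codons once -> uniform
  allcds <- paste0(paste(dna(sense_codons()), collapse = ""), "TAA")
  t2 <- codon_frequencies(allcds)
  expect_true(all(abs(t2$freq - 100 / 61) < 1e-12))
  expect_equal(sum(t2$freq), 100, tolerance = 1e-12)
  # internal stops and ambiguous codons are excluded but accounted
  t3 <- codon_frequencies("AAATAACCCNNNTTT")
  expect_equal(attr(t3, "total_codons"), 3L)
  expect_equal(attr(t3, "qc")$internal_stops, 1L)
  expect_equal(attr(t3, "qc")$ambiguous_codons, 1L)
  expect_error(codon_frequencies(character()), "no CDS")
  expect_error(codon_frequencies("AC"), "at least 3")
})

test_that("large samples from the published host column are recovered", {
  cu <- load_codon_usage_fixture()
  host <- setNames(cu$host$freq, cu$host$codon)
  cds <- withr::with_seed(424242, {
    codons <- sample(names(host), 100000, replace = TRUE, prob = host)
    split_at <- rep(seq_len(100), each = 1000)
    vapply(split(codons, split_at),
           function(x) paste0(paste(dna(x), collapse = ""), "TAA"),
           character(1))
  })
  tab <- codon_frequencies(cds)
  got <- setNames(tab$freq, tab$codon)
  expect_true(all(abs(got - host[names(got)] / sum(host) * 100) < 0.15))
})

test_that("gc_content excludes ambiguous bases", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCATNN"), 50)
  expect_error(gc_content("NNNN"), "unambiguous")
  expect_error(gc_content(""), "empty")
})

test_that("the ratio statistic is mean-then-divide with printed values", {
  cu <- load_codon_usage_fixture()
  rat <- cub_ratio(list(cu$pbcv1, cu$an69c), cu$host)
  r <- setNames(rat$ratio, rat$codon)
  expect_equal(round_half_up(r[["AUA"]]), 12.70)
  expect_equal(round_half_up(r[["AAA"]]), 16.92)
  expect_equal(round_half_up(r[["UUA"]]), 26.67)
  expect_equal(round_half_up(r[["AAG"]]), 0.87)
  # the printed GAU ratio fails the footnote formula: a documented erratum
  expect_equal(round_half_up(r[["GAU"]]), 2.33)
  printed <- setNames(cu$fixture$ratio_printed, cu$fixture$codon)
  expect_gt(abs(r[["GAU"]] - printed[["GAU"]]), 2)
  # identical tables give ratio 1 everywhere
  same <- cub_ratio(cu$host, cu$host)
  expect_true(all(abs(same$ratio[same$f_host > 0] - 1) < 1e-12))
  expect_true(all(same$favored[same$f_host > 0] == "boundary"))
})

test_that("zero host frequency yields an undefined ratio, not infinity", {
  host <- setNames(rep(100 / 60, 61), sense_codons())
  host["AUA"] <- 0
  virus <- uniform_codon_table()
  rat <- cub_ratio(codon_usage_from_percent(virus, "v"),
                   codon_usage_from_percent(host, "h"))
  expect_true(is.na(rat$ratio[rat$codon == "AUA"]))
  expect_equal(rat$favored[rat$codon == "AUA"], "undefined")
  expect_error(tils_benefit(rat), "undefined")
})

test_that("frequencies and ratios are scale invariant", {
  base <- c("AAATTTGGGCCCACG")
  reps <- paste(rep(base, 17), collapse = "")
  t1 <- codon_frequencies(base)
  t2 <- codon_frequencies(reps)
  expect_equal(t1$freq, t2$freq, tolerance = 1e-12)
  u <- codon_usage_from_percent(uniform_codon_table(), "u")
  expect_equal(cub_ratio(t1, u)$ratio, cub_ratio(t2, u)$ratio,
               tolerance = 1e-12)
})

test_that("preferred codons reflect the GC-rich host vs AT-rich virus bias", {
  cu <- load_codon_usage_fixture()
  host_pref <- preferred_codons(cu$host)
  expect_equal(host_pref$codon[host_pref$amino_acid == "G"], "GGC")
  expect_equal(host_pref$codon[host_pref$amino_acid == "E"], "GAG")
  virus_pref <- preferred_codons(cu$pbcv1)
  expect_equal(virus_pref$codon[virus_pref$amino_acid == "E"], "GAA")
  expect_true(virus_pref$codon[virus_pref$amino_acid == "K"] == "AAA")
  uni <- preferred_codons(codon_usage_from_percent(uniform_codon_table()))
  multi <- names(which(table(codon_to_aa(sense_codons())) > 1))
  expect_true(all(uni$tie[uni$amino_acid %in% multi]))
  expect_false(any(uni$tie[!uni$amino_acid %in% multi]))
})

test_that("favorability counts assisting codons at the tau = 1 threshold", {
  cu <- load_codon_usage_fixture()
  rat <- cub_ratio(list(cu$pbcv1, cu$an69c), cu$host)
  rec <- fixture_recognized_codons()
  inv <- tibble::tibble(
    amino_acid = codon_to_aa(rec$pbcv1, three_letter = TRUE),
    codon = rec$pbcv1, anticodon = codon_to_anticodon(rec$pbcv1),
    pseudogene = FALSE, identity_known = TRUE)
  fav <- classify_favorability(inv, rat)
  expect_equal(fav$n_distinct_codons, 8)
  expect_equal(fav$n_assisting, 7)     # all but Lys-AAG (ratio 0.87)
  neutral <- fav$codons$codon[fav$codons$label != "assisting"]
  expect_identical(neutral, "AAG")
  # all-assisting synthetic table
  allv <- codon_usage_from_percent(
    setNames(c(rep(99 / 60, 60), 100 - 99), c(setdiff(sense_codons(), "AAG"),
                                              "AAG")), "v")
  rat2 <- cub_ratio(allv, codon_usage_from_percent(uniform_codon_table()))
  fav2 <- classify_favorability(inv, rat2)
  expect_lte(fav2$n_assisting, fav2$n_distinct_codons)
  # per-gene counting: three Asn(AAC) genes vs one distinct codon
  inv3 <- tibble::tibble(amino_acid = "Asn", codon = "AAC", anticodon = "GUU",
                         pseudogene = FALSE, identity_known = TRUE)[c(1, 1, 1), ]
  favd <- classify_favorability(inv3, rat)
  favg <- classify_favorability(inv3, rat,
                                favorability_params(counting = "per_gene"))
  expect_equal(favd$n_assisting, 1)
  expect_equal(favg$n_assisting, 3)
  # pseudogenes are excluded with a warning
  inv4 <- inv
  inv4$pseudogene[1] <- TRUE
  expect_warning(classify_favorability(inv4, rat), "excluded")
})

test_that("wobble and TilS options extend the recognized set", {
  cu <- load_codon_usage_fixture()
  rat <- cub_ratio(list(cu$pbcv1, cu$an69c), cu$host)
  inv <- tibble::tibble(amino_acid = c("Tyr", "Met"),
                        codon = c("UAC", "AUG"),
                        anticodon = c("GUA", "CAU"),
                        pseudogene = FALSE, identity_known = TRUE)
  plain <- classify_favorability(inv, rat)
  expect_setequal(plain$codons$codon, c("UAC", "AUG"))
  wob <- classify_favorability(inv, rat,
                               favorability_params(use_wobble = TRUE))
  expect_setequal(wob$codons$codon, c("UAC", "UAU", "AUG"))
  tils <- classify_favorability(inv, rat,
                                favorability_params(apply_tils = TRUE))
  expect_setequal(tils$codons$codon, c("UAC", "AUA"))
})

test_that("the TilS benefit is the assisting AUA ratio", {
  cu <- load_codon_usage_fixture()
  rat <- cub_ratio(list(cu$pbcv1, cu$an69c), cu$host)
  tb <- tils_benefit(rat)
  expect_equal(round_half_up(tb$ratio), 12.70)
  expect_equal(tb$label, "assisting")
  same <- cub_ratio(cu$host, cu$host)
  expect_equal(tils_benefit(same)$label, "boundary")
})
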