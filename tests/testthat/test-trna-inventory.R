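# Anticodon-codon recognition, wobble, TilS, intron geometry, promoter
# boxes, CCA status, inventory construction.

test_that("anticodon_to_codon is the antiparallel reverse complement", {
  expect_identical(anticodon_to_codon("CAU"), "AUG")  # tRNA-Met reads AUG
  expect_identical(anticodon_to_codon("GUA"), "UAC")  # tRNA-Tyr reads UAC
  expect_error(anticodon_to_codon("CAT"), "RNA")
  expect_error(anticodon_to_codon("CA"), "RNA")
  b <- c("A", "C", "G", "U")
  all64 <- apply(expand.grid(b, b, b), 1, paste, collapse = "")
  expect_identical(anticodon_to_codon(anticodon_to_codon(all64)), all64)
})

test_that("wobble sets expand G34 and are supersets of the strict codon", {
  expect_identical(wobble_recognition_set("GUA"), c("UAC", "UAU"))
  expect_identical(wobble_recognition_set("CAU"), "AUG")  # C34 does not wobble
  strict <- wobble_rules(enabled = FALSE)
  b <- c("A", "C", "G", "U")
  all64 <- apply(expand.grid(b, b, b), 1, paste, collapse = "")
  for (ac in all64) {
    expect_identical(wobble_recognition_set(ac, strict),
                     anticodon_to_codon(ac))
    expect_true(anticodon_to_codon(ac) %in% wobble_recognition_set(ac))
  }
  expect_error(wobble_rules(pairings = list(G = "U")), "Watson-Crick")
})

test_that("TilS recoding rewrites Met/CAU to read AUA, once", {
  met <- tibble::tibble(amino_acid = "Met", codon = "AUG", anticodon = "CAU")
  rec <- apply_tils(met)
  expect_identical(rec$amino_acid, "Ile")
  expect_identical(rec$codon, "AUA")
  expect_identical(rec$recognition[[1]], "AUA")
  expect_true(rec$tils_recoded)
  expect_identical(met$amino_acid, "Met")  # input unmodified
  expect_error(apply_tils(rec), "tRNA-Met")
  tyr <- tibble::tibble(amino_acid = "Tyr", codon = "UAC", anticodon = "GUA")
  expect_error(apply_tils(tyr), "tRNA-Met")
})

test_that("intron geometry is recovered exactly across a length sweep", {
  for (len in c(10L, 11L, 13L, 14L)) {
    g <- generate_trna_gene_sequence("Tyr", "GUA",
                                     intron = list(offset = 1, length = len))
    geom <- intron_geometry(list(sequence = paste0(
      substr(g$sequence, g$exons$start[1], g$exons$end[1]),
      substr(g$sequence, g$exons$start[2], g$exons$end[2])),
      anticodon = "GUA", strand = "+", exons = g$exons))
    expect_equal(geom$offset, 1L)
    expect_equal(geom$length, len)
  }
  single <- generate_trna_gene_sequence("Tyr", "GUA")
  expect_null(intron_geometry(list(sequence = single$sequence,
                                   anticodon = "GUA", strand = "+",
                                   exons = NULL)))
  expect_error(
    intron_geometry(list(sequence = strrep("G", 80), anticodon = "GUA",
                         strand = "+",
                         exons = data.frame(start = c(1, 50),
                                            end = c(40, 90)))),
    "not locatable")
})

test_that("Box A/B scan finds embedded boxes and respects the A-before-B rule", {
  g <- generate_trna_gene_sequence("Asn", "GUU")
  hits <- find_polIII_boxes(g$sequence)
  perfect <- hits[hits$mismatches == 0, ]
  expect_setequal(perfect$box, c("A", "B"))
  expect_equal(perfect$offset[perfect$box == "A"], 8L)
  expect_equal(perfect$offset[perfect$box == "B"], 49L)
  expect_true(all(hits$offset[hits$box == "A"] <
                    min(hits$offset[hits$box == "B"])))
  # no hits in a boxless sequence at zero mismatch budget
  none <- find_polIII_boxes(strrep("ACAC", 50),
                            box_motif_config(max_mismatches = 0))
  expect_equal(nrow(none), 0)
  # too short for any window
  expect_equal(nrow(find_polIII_boxes("ACGTACGT")), 0)
})

test_that("CCA detection reads the coding strand and is strand-symmetric", {
  g <- generate_trna_gene_sequence("Asn", "GUU")
  expect_false(detect_cca_end(g$sequence))       # generator default: no CCA
  expect_true(detect_cca_end("GGGTTTGGTCCA"))
  expect_true(detect_cca_end("ggguuugguCCA"))
  # a minus-strand gene stores plus-strand coordinates; its coding-strand
  # sequence (what build_inventory stores) gives the same answer
  gen <- make_test_virus(seed = 120, codons = c("AAC", "AGA"), spacers = 7,
                         genome_length = 3000, strand = "-")
  inv <- build_inventory(gen$record)
  expect_true(all(inv$strand == "-"))
  expect_false(any(inv$cca))
})

test_that("build_inventory reproduces the 14-gene reference order", {
  gen <- make_test_virus(seed = 121)
  inv <- build_inventory(gen$record)
  expect_equal(nrow(inv), 14)
  expect_identical(inv$codon, ma1e_codons())
  expect_identical(inv$spacer_to_next[-14], as.integer(ma1e_spacers()))
  expect_identical(
    inv$amino_acid,
    c("Leu", "Ile", "Asn", "Leu", "Arg", "Asn", "Gly", "Asn", "Lys", "Gln",
      "Lys", "Tyr", "Lys", "Lys"))
  # order-stability: permuting the feature rows changes nothing
  rec2 <- gen$record
  perm <- withr::with_seed(1, sample(nrow(rec2$features)))
  rec2$features <- rec2$features[perm, ]
  rec2$features <- rec2$features[order(rec2$features$start,
                                       rec2$features$end), ]
  expect_identical(build_inventory(rec2)$codon, inv$codon)
})

test_that("inventory keeps pseudogenes and flags identity-unknown tRNAs", {
  gen <- make_test_virus(seed = 122, codons = c("AAC", "AGA", "GGA"),
                         spacers = c(5, 9), genome_length = 3000)
  rec <- gen$record
  tr_idx <- which(rec$features$kind == "tRNA")
  rec$features$pseudo[tr_idx[2]] <- TRUE
  rec$features$anticodon[tr_idx[3]] <- NA
  rec$features$product[tr_idx[3]] <- "hypothetical tRNA"
  expect_warning(build_inventory(rec), "identity-unknown")
  inv <- suppressWarnings(build_inventory(rec))
  expect_equal(nrow(inv), 3)        # nothing dropped
  expect_true(inv$pseudogene[2])
  expect_false(inv$identity_known[3])
  # product-string fallback: "tRNA-Tyr (GTA)" resolves without /anticodon
  rec$features$anticodon[tr_idx[3]] <- NA
  rec$features$product[tr_idx[3]] <- "tRNA-Gly (TCC)"
  inv2 <- build_inventory(rec)
  expect_identical(inv2$codon[3], "GGA")
  expect_true(inv2$identity_known[3])
})

test_that("empty genomes give empty inventories", {
  rec <- genome_record("none", strrep("ACGT", 100))
  expect_equal(nrow(build_inventory(rec)), 0)
})
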