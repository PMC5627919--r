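test_that("greedy clustering separates divergent groups by abundance order", {
  set.seed(51)
  a <- rand_bases(313)
  a1 <- mutate_at(a, sample.int(313, 3))    # ~1% divergent: same cluster
  b <- mutate_at(a, sample.int(313, 47))    # ~15% divergent: new cluster
  d <- dereplicate(c(rep(a, 10), rep(a1, 5), rep(b, 3)))
  cl <- greedy_cluster(d, 97)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, `[[`, numeric(1), "total_abundance"), c(15, 3))
  expect_equal(cl[[1]]$centroid, a)
  expect_equal(cl[[2]]$centroid, b)
})

test_that("degenerate clustering inputs behave", {
  d <- dereplicate(rep("ACGTACGTACGT", 7))
  cl <- greedy_cluster(d)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$centroid, "ACGTACGTACGT")
  expect_equal(cl[[1]]$total_abundance, 7)
  expect_length(greedy_cluster(dereplicate(character(0))), 0L)
})

test_that("translation follows the selected genetic code", {
  # invertebrate mitochondrial (table 5): AGA = Ser, TGA = Trp
  expect_equal(translate_dna("ATGAGATGA", 0, "5"), "MSW")
  expect_equal(translate_dna("ATGAGATGA", 0, "1"), "MR*")
  expect_equal(translate_dna("TAA", 0, "1"), "*")
  expect_equal(translate_dna("TAA", 0, "5"), "*")
  expect_equal(translate_dna("ATAACG", 0, "5"), "MT")   # ATA = Met in table 5
  expect_equal(translate_dna("ATAACG", 0, "1"), "IT")
  expect_equal(translate_dna("ATGANATGA", 0, "5"), "MXW")  # fuzzy codon
  expect_equal(translate_dna("AATGAGATGA", 1, "5"), "MSW") # frame offset
  expect_equal(translate_dna("ATGAGATG", 0, "5"), "MS")    # partial codon drop
  expect_error(translate_dna("AC", 0, "5"), "codon")
})

test_that("coding screen finds the stop-free frame of simulated barcodes", {
  ref <- tiny_reference(seed = 61)
  for (i in seq_len(3)) {
    scr <- coding_screen(ref$specimens$bases[i], ref$panel)
    expect_true(scr$stop_free)
    expect_equal(scr$best_frame, 0L)
  }
})

test_that("coding screen rejects sequences with stops in all frames", {
  set.seed(62)
  base <- rand_bases(90)
  # plant a TAA in each of the three frames
  v <- strsplit(base, "", fixed = TRUE)[[1]]
  v[10:12] <- c("T", "A", "A")   # frame 0 codon 4
  v[14:16] <- c("T", "A", "A")   # frame 1
  v[18:20] <- c("T", "A", "A")   # frame 2
  ref <- tiny_reference(seed = 61)
  scr <- coding_screen(paste(v, collapse = ""), ref$panel)
  expect_false(scr$stop_free)
  expect_equal(classify_cluster(scr, ref$panel)$taxon_label, "unknown")
  short <- coding_screen(rand_bases(20), ref$panel)
  expect_false(isTRUE(short$ok))
  expect_equal(short$reason, "too short")
})

test_that("classification labels target, contaminant and unknown clusters", {
  ref <- tiny_reference(seed = 63)
  scr <- coding_screen(ref$specimens$bases[1], ref$panel)
  cls <- classify_cluster(scr, ref$panel)
  expect_equal(cls$taxon_label, "target_COI")
  expect_gte(cls$aa_identity, 95)
  scr <- coding_screen(ref$decoys[[1]], ref$panel)
  cls <- classify_cluster(scr, ref$panel)
  expect_equal(cls$taxon_label, "bacterial_COI")
  expect_equal(cls$aa_identity, 100)
})

test_that("barcode recovery returns the exact truth with expected support", {
  cfg <- sim_config(n_species = 3, specimens_per_species = 1,
                    reads_per_specimen = 600,
                    contamination_fraction = 0.15, chimera_fraction = 0.05,
                    seed = 71)
  ref <- simulate_reference_species(cfg)
  pr <- coi_primers()
  rs <- simulate_specimen_readset(ref$specimens$bases[1], cfg, ref$decoys,
                                  "s1", seed = 72)
  # quality/primer/length filtered reads; chimera removal runs inside
  tr <- locate_and_trim_primers(rs$reads, pr$forward, pr$reverse)
  rec <- recover_barcode(length_filter(tr$records), ref$panel, "s1")
  expect_true(rec$success)
  expect_equal(rec$bases, ref$specimens$bases[1])
  expect_lt(abs(rec$support - 0.8), 0.05)
  expect_length(rec$flags, 0L)
})

test_that("a contaminant-majority specimen is recovered but flagged", {
  cfg <- sim_config(n_species = 3, specimens_per_species = 1,
                    reads_per_specimen = 500, n_decoys = 1,
                    contamination_fraction = 0.6, chimera_fraction = 0,
                    seed = 73)
  ref <- simulate_reference_species(cfg)
  pr <- coi_primers()
  rs <- simulate_specimen_readset(ref$specimens$bases[2], cfg, ref$decoys,
                                  "s2", seed = 74)
  pp <- preprocess_reads(rs$reads, pr$forward, pr$reverse)
  rec <- recover_barcode(pp$uniques, ref$panel, "s2")
  expect_true(rec$success)
  expect_equal(rec$bases, ref$specimens$bases[2])
  expect_true("contaminant-majority" %in% rec$flags)
})

test_that("contaminant-only and empty read sets give failure records", {
  ref <- tiny_reference(seed = 75)
  decoy_reads <- reads_of(ref$decoys[[1]], 50)
  rec <- recover_barcode(decoy_reads, ref$panel, "only-bact")
  expect_false(rec$success)
  expect_equal(rec$reason, "no qualifying cluster")
  expect_true("bacterial_COI" %in% rec$clusters$taxon_label)
  empty <- recover_barcode(dereplicate(character(0)), ref$panel, "none")
  expect_false(empty$success)
  expect_equal(empty$reason, "no reads")
})

test_that("recovery is invariant to read order", {
  cfg <- sim_config(n_species = 2, specimens_per_species = 1,
                    reads_per_specimen = 200, seed = 76)
  ref <- simulate_reference_species(cfg)
  pr <- coi_primers()
  rs <- simulate_specimen_readset(ref$specimens$bases[1], cfg, ref$decoys,
                                  "s", seed = 77)
  pp <- preprocess_reads(rs$reads, pr$forward, pr$reverse)
  rec1 <- recover_barcode(pp$uniques, ref$panel, "s")
  set.seed(78)
  shuffled <- rs$reads[sample.int(nrow(rs$reads)), , drop = FALSE]
  pp2 <- preprocess_reads(seq_records(shuffled$id, shuffled$bases,
                                      shuffled$desc, shuffled$qual),
                          pr$forward, pr$reverse)
  rec2 <- recover_barcode(pp2$uniques, ref$panel, "s")
  expect_equal(rec1$bases, rec2$bases)
  expect_equal(rec1$support, rec2$support)
})

test_that("consensus mode outvotes an erroneous centroid", {
  ref <- tiny_reference(seed = 81)
  truth <- ref$specimens$bases[1]
  # third-position substitutions in codons not starting "TA" are stop-safe
  cod <- substring(truth, seq(1, 311, 3), seq(3, 313, 3))
  safe <- which(substr(cod, 1, 2) != "TA")[1:3]
  pos <- safe * 3L
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  err_read <- function(p) {
    v <- strsplit(truth, "", fixed = TRUE)[[1]]
    v[p] <- transit[[v[p]]]
    paste(v, collapse = "")
  }
  # the most abundant unique carries an error; the truth never appears
  reads <- c(rep(err_read(pos[1]), 3), rep(err_read(pos[2]), 2),
             rep(err_read(pos[3]), 2))
  cent <- recover_barcode(dereplicate(reads), ref$panel, "s")
  cons <- recover_barcode(dereplicate(reads), ref$panel, "s",
                          representative = "consensus")
  expect_equal(cent$bases, err_read(pos[1]))
  expect_equal(cons$bases, truth)
})

test_that("build_database validates ids and taxonomy coverage", {
  ref <- tiny_reference(seed = 79)
  bc <- data.frame(specimen_id = ref$specimens$specimen_id[1:4],
                   species = ref$specimens$species_id[1:4],
                   bases = ref$specimens$bases[1:4], stringsAsFactors = FALSE)
  db <- build_database(bc, ref$taxonomy, "indigenous")
  expect_s3_class(db, "reference_db")
  expect_length(db$seq, 4L)
  expect_equal(length(unique(db$taxonomy$species)), 2L)
  expect_error(build_database(rbind(bc, bc[1, ]), ref$taxonomy), "duplicate")
  bad <- bc; bad$specimen_id[1] <- "nowhere"
  expect_error(build_database(bad, ref$taxonomy), "nowhere")
  expect_warning(db0 <- build_database(bc[0, ], ref$taxonomy), "empty")
  expect_length(db0$seq, 0L)
})

test_that("reference databases round-trip through FASTA + TSV", {
  ref <- tiny_reference(seed = 80)
  bc <- data.frame(specimen_id = ref$specimens$specimen_id,
                   species = ref$specimens$species_id,
                   bases = ref$specimens$bases, stringsAsFactors = FALSE)
  db <- build_database(bc, ref$taxonomy, "indigenous")
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_reference_db(db, fa, tsv)
  back <- read_reference_db(fa, tsv, "indigenous")
  expect_equal(back$seq, db$seq)
  expect_equal(back$taxonomy, db$taxonomy)
})
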