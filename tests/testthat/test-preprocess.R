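pr <- coi_primers()

test_that("quality filter applies the expected-error and mean-quality rules", {
  keep <- quality_filter(seq_records("a", rand_bases(250),
                                     qual = qual_const(40L, 250)))
  expect_true(keep)   # expected errors = 250 * 1e-4 = 0.025
  expect_false(quality_filter(seq_records("b", rand_bases(250),
                                          qual = qual_const(2L, 250))))
  # 200 bp at Q23: expected errors = 200 * 10^-2.3 ~ 1.002 > 1.0
  expect_equal(200 * 10^(-2.3) > 1.0, TRUE)
  expect_false(quality_filter(seq_records("c", rand_bases(200),
                                          qual = qual_const(23L, 200))))
  expect_error(quality_filter(seq_records("d", "ACGT")), "qualities")
})

test_that("primer location trims exact amplicons and keeps the insert", {
  set.seed(21)
  insert <- rand_bases(313)
  read <- paste0(gsub("W", "A", gsub("Y", "C", pr$forward)), insert,
                 reverse_complement(gsub("R", "A", gsub("Y", "C", pr$reverse))))
  rec <- seq_records("r1", read, qual = qual_const(30L, nchar(read)))
  out <- locate_and_trim_primers(rec, pr$forward, pr$reverse)
  expect_equal(out$records$bases, insert)
  expect_equal(out$records$orientation, "forward")
  expect_equal(out$log$fate, "kept")
})

test_that("a reverse-complemented amplicon is re-oriented to the same insert", {
  set.seed(22)
  insert <- rand_bases(313)
  fwd_i <- gsub("W", "T", gsub("Y", "T", pr$forward))
  rev_i <- gsub("R", "G", gsub("Y", "T", pr$reverse))
  read <- paste0(fwd_i, insert, reverse_complement(rev_i))
  both <- seq_records(c("fwd", "rev"), c(read, reverse_complement(read)),
                      qual = qual_const(30L, nchar(read)))
  out <- locate_and_trim_primers(both, pr$forward, pr$reverse)
  expect_equal(out$records$bases[1], out$records$bases[2])
  expect_equal(out$records$orientation, c("forward", "reverse"))
})

test_that("reads beyond two forward-primer mismatches are rejected", {
  set.seed(23)
  insert <- rand_bases(313)
  fwd_i <- gsub("W", "A", gsub("Y", "C", pr$forward))
  # 3 substitutions at non-degenerate primer positions (G at 1,2 and T at 11)
  broken <- fwd_i
  substr(broken, 1, 2) <- "TT"
  substr(broken, 11, 11) <- "A"
  read2 <- paste0(broken, insert)
  rec <- seq_records("bad", read2, qual = qual_const(30L, nchar(read2)))
  out <- locate_and_trim_primers(rec, pr$forward, pr$reverse)
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$log$fate, "rejected")
  # two mismatches pass
  two <- fwd_i
  substr(two, 1, 2) <- "TT"
  rec2 <- seq_records("ok", paste0(two, insert),
                      qual = qual_const(30L, nchar(read2)))
  expect_equal(locate_and_trim_primers(rec2, pr$forward, pr$reverse)$log$fate,
               "kept")
})

test_that("length filter removes exactly the reads under the threshold", {
  rec <- seq_records(c("a", "b", "c"),
                     c(rand_bases(199), rand_bases(200), rand_bases(313)))
  kept <- length_filter(rec, 200)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(nrow(length_filter(rec[0, ], 200)), 0L)
  expect_equal(length_filter(kept, 200), kept)  # idempotent
})

test_that("dereplication counts, sorts and tracks per-sample abundances", {
  d <- dereplicate(c("AAA", "AAA", "CCC"))
  expect_equal(d$bases, c("AAA", "CCC"))
  expect_equal(d$abundance, c(2L, 1L))
  expect_equal(sum(d$abundance), 3L)
  d2 <- dereplicate(c("TTT", "GGG", "CCC"))
  expect_equal(d2$abundance, c(1L, 1L, 1L))
  expect_equal(d2$bases, sort(d2$bases))  # abundance ties break lexicographically
  d3 <- dereplicate(rep("AAA", 3), sample_labels = c("s1", "s1", "s2"))
  expect_equal(as.vector(d3$samples), c(2L, 1L))
  expect_equal(colnames(d3$samples), c("s1", "s2"))
})

test_that("dereplication is invariant to read order", {
  set.seed(31)
  reads <- sample(c(rep("ACGTACGT", 5), rep("TTGGCCAA", 3), "GATTACA"))
  expect_equal(dereplicate(reads), dereplicate(rev(reads)))
})

test_that("a constructed two-parent chimera is flagged with its crossover", {
  set.seed(41)
  a <- rand_bases(313)
  # ~10% divergent parents; differences pinned at 148 and 152 so the
  # crossover at 150 is identifiable to within a few bases
  pos <- unique(c(148L, 152L, sample(setdiff(1:313, 145:155), 29)))
  b <- mutate_at(a, pos)
  chimera <- paste0(substr(a, 1, 150), substr(b, 151, 313))
  d <- dereplicate(c(rep(a, 10), rep(b, 10), chimera))
  res <- detect_chimeras(d)
  qi <- which(d$bases == chimera)
  expect_true(res$flagged[qi])
  expect_lte(abs(res$crossover[qi] - 150), 5)
  expect_equal(sort(d$bases[c(res$parent_a[qi], res$parent_b[qi])]),
               sort(c(a, b)))
})

test_that("non-chimeric uniques are not flagged", {
  set.seed(42)
  a <- rand_bases(313)
  d <- dereplicate(c(rep(a, 10), rep(mutate_at(a, 5), 4), a))
  res <- detect_chimeras(d)
  expect_false(any(res$flagged[d$bases == a]))   # identical to a parent
  expect_false(res$flagged[1])                   # most abundant: no parents
})

test_that("chimera detection hits constructed chimeras and spares clean sets", {
  set.seed(43)
  a <- rand_bases(313)
  diff_pos <- sort(sample.int(313, 20))
  b <- mutate_at(a, diff_pos)  # ~6% divergent parents
  # one crossover per parent-difference gap: every chimera is a distinct
  # molecule (crossovers inside the same gap would yield identical strings)
  ks <- diff_pos[4:16]
  chims <- vapply(ks, function(k)
    paste0(substr(a, 1, k), substr(b, k + 1, 313)), character(1))
  d <- dereplicate(c(rep(a, 200), rep(b, 150), chims))
  res <- detect_chimeras(d)
  flagged <- d$bases[res$flagged]
  expect_gte(sum(unique(chims) %in% flagged) / length(unique(chims)), 0.8)
  expect_false(a %in% flagged)
  expect_false(b %in% flagged)
})

test_that("preprocess_reads runs the full stage order and logs fates", {
  set.seed(44)
  cfg <- sim_config(n_species = 2, seed = 3)
  ref <- simulate_reference_species(cfg)
  rs <- simulate_specimen_readset(ref$specimens$bases[1], cfg, ref$decoys,
                                  "sp", seed = 5)
  # append reads that must fall to each filter stage
  fwd_i <- gsub("W", "A", gsub("Y", "C", pr$forward))
  broken <- fwd_i
  substr(broken, 4, 5) <- "TT"   # A, C: non-degenerate primer positions
  substr(broken, 7, 7) <- "A"    # G
  extra <- seq_records(
    c("lowq", "badprimer", "short"),
    c(rand_bases(365), paste0(broken, rand_bases(313)),
      paste0(fwd_i, rand_bases(60))),
    qual = c(qual_const(4L, 365), qual_const(30L, 339), qual_const(30L, 86)))
  reads <- rbind(rs$reads, extra)
  class(reads) <- class(rs$reads)
  pp <- preprocess_reads(reads, pr$forward, pr$reverse)
  expect_equal(nrow(pp$log), nrow(reads))
  expect_lte(pp$n_retained, pp$n_input)
  expect_equal(pp$n_retained, sum(pp$log$fate == "kept"))
  fate <- setNames(pp$log$reason, pp$log$id)
  expect_match(fate[["lowq"]], "quality")
  expect_match(fate[["badprimer"]], "primer")
  expect_match(fate[["short"]], "short")
})
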