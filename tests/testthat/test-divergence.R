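test_that("site counting separates transitions, transversions and exclusions", {
  set.seed(81)
  a <- rand_bases(100)
  # 10 transitions and 5 transversions at distinct positions
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  transv <- c(A = "C", G = "T", C = "A", T = "G")
  pos <- sample.int(100, 15)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- av
  bv[pos[1:10]] <- transit[av[pos[1:10]]]
  bv[pos[11:15]] <- transv[av[pos[11:15]]]
  cnt <- count_sites(a, paste(bv, collapse = ""))
  expect_equal(cnt$n_valid, 100L)
  expect_equal(cnt$P, 0.10)
  expect_equal(cnt$Q, 0.05)
  same <- count_sites(a, a)
  expect_equal(c(same$P, same$Q), c(0, 0))
  # pairwise deletion: an N drops one site
  bn <- av; bn[1] <- "N"
  cn <- count_sites(a, paste(bn, collapse = ""))
  expect_equal(cn$n_valid, 99L)
  expect_equal(c(cn$P, cn$Q), c(0, 0))
  expect_error(count_sites("NNN", "ACG"), "no comparable sites")
  expect_error(count_sites("ACGT", "ACG"), "equal length")
})

test_that("the K2P closed form evaluates and saturates correctly", {
  expect_equal(k2p_distance(list(P = 0.10, Q = 0.05)),
               -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  expect_equal(k2p_distance(list(P = 0.10, Q = 0.05)), 0.170181,
               tolerance = 1e-6)
  expect_equal(k2p_distance(list(P = 0, Q = 0)), 0)
  expect_error(k2p_distance(list(P = 0.5, Q = 0.1)), class = "k2p_saturation")
})

test_that("K2P is monotone in P and Q over the valid domain", {
  grid <- seq(0.01, 0.2, by = 0.01)
  for (Q in c(0, 0.05, 0.1)) {
    d <- vapply(grid, function(P) k2p_distance(list(P = P, Q = Q)), numeric(1))
    expect_true(all(diff(d) > 0))
  }
  for (P in c(0, 0.05, 0.1)) {
    d <- vapply(grid, function(Q) k2p_distance(list(P = P, Q = Q)), numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("k2p_matrix agrees with the ape K80 implementation", {
  set.seed(82)
  seqs <- setNames(vapply(1:8, function(i) rand_bases(400), character(1)),
                   paste0("t", 1:8))
  base <- rand_bases(400)
  seqs[] <- vapply(1:8, function(i) mutate_at(base, sample.int(400, 8 * i)),
                   character(1))
  ours <- k2p_matrix(seqs)
  bin <- ape::as.DNAbin(t(vapply(seqs, function(s)
    strsplit(tolower(s), "", fixed = TRUE)[[1]], character(400))))
  theirs <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(unclass(ours), theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(ours)))
  expect_equal(diag(ours), setNames(rep(0, 8), names(seqs)))
})

test_that("intraspecific divergence summarizes pairwise K2P per species", {
  # three conspecific sequences plus singletons and an identical pair
  set.seed(83)
  s <- rand_bases(300)
  seqs <- c(a1 = s, a2 = mutate_at(s, sample.int(300, 3)),
            a3 = mutate_at(s, sample.int(300, 6)),
            b1 = rand_bases(300), b2 = rand_bases(300),
            c1 = mutate_at(s, 150:200))
  tax <- data.frame(ref_id = names(seqs),
                    species = c("A", "A", "A", "B", "B", "C"),
                    group = "Rotifera", lineage = "", stringsAsFactors = FALSE)
  db <- reference_db(names(seqs), seqs, tax)
  out <- intraspecific_divergence(db)
  rowA <- out[out$species == "A", ]
  expect_equal(rowA$n_pairs, 3L)
  m <- k2p_matrix(seqs[1:3])
  expect_equal(rowA$mean_k2p, mean(m[upper.tri(m)]))
  expect_equal(rowA$max_k2p, max(m[upper.tri(m)]))
  expect_equal(out[out$species == "C", "n_pairs"], 0L)
  expect_true(is.na(out[out$species == "C", "mean_k2p"]))
  # identical conspecific pair
  db2 <- reference_db(c("x1", "x2"), c(s, s),
                      data.frame(ref_id = c("x1", "x2"), species = "X",
                                 group = "Copepoda", lineage = ""))
  out2 <- intraspecific_divergence(db2)
  expect_equal(out2$mean_k2p, 0)
  expect_equal(out2$max_k2p, 0)
})

test_that("discrimination_check finds pairs without a barcode gap", {
  set.seed(84)
  s <- rand_bases(300)
  seqs <- c(a1 = s, a2 = mutate_at(s, sample.int(300, 15)),   # intra ~5%
            b1 = mutate_at(s, 1:9),                           # inter ~3% to A
            c1 = rand_bases(300), c2 = rand_bases(300))
  tax <- data.frame(ref_id = names(seqs),
                    species = c("A", "A", "B", "C", "C"),
                    group = "Cladocera", lineage = "", stringsAsFactors = FALSE)
  db <- reference_db(names(seqs), seqs, tax)
  un <- discrimination_check(db)
  expect_true(any(un$species_a == "A" & un$species_b == "B"))
  expect_false(any(un$species_a == "A" & un$species_b == "C"))
  # shared identical barcode is always unresolved
  db2 <- reference_db(c("p1", "q1"), c(s, s),
                      data.frame(ref_id = c("p1", "q1"),
                                 species = c("P", "Q"),
                                 group = "Rotifera", lineage = ""))
  un2 <- discrimination_check(db2)
  expect_equal(nrow(un2), 1L)
  expect_equal(un2$min_interspecific, 0)
})

test_that("NJ handles two and three taxa by the closed formulas", {
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(m2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(0.2, 0.2))
  m3 <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(m3)
  cp <- ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")]
  # three-point formulas: x = (dAB + dAC - dBC)/2 etc.
  expect_equal(cp, m3, tolerance = 1e-12, ignore_attr = TRUE)
  xa <- (0.3 + 0.5 - 0.6) / 2
  expect_equal(t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "A")], xa)
  expect_error(nj_tree(m2[1, 1, drop = FALSE]), "two taxa")
})

test_that("NJ reconstructs random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(85)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.01, 0.3))
    m <- ape::cophenetic.phylo(true)
    ours <- nj_tree(m[true$tip.label, true$tip.label])
    expect_equal(phangorn::RF.dist(ours, true), 0)
    cp <- ape::cophenetic.phylo(ours)[true$tip.label, true$tip.label]
    expect_lt(max(abs(cp - m[true$tip.label, true$tip.label])), 1e-9)
  }
})

test_that("NJ agrees with the ape implementation on noisy matrices", {
  skip_if_not_installed("phangorn")
  set.seed(86)
  for (i in 1:5) {
    base <- rand_bases(500)
    seqs <- setNames(vapply(1:7, function(k)
      mutate_at(base, sample.int(500, 10 * k)), character(1)), paste0("t", 1:7))
    m <- k2p_matrix(seqs)
    expect_equal(phangorn::RF.dist(nj_tree(m), ape::nj(m)), 0)
  }
})

test_that("negative branch estimates are clamped and logged", {
  # a deliberately non-additive matrix known to produce a negative estimate
  m <- matrix(c(0, 2, 2, 2.1,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                2.1, 2, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(m)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_deficit"), 0)
})

test_that("bootstrap gives near-certain support to a strong sister pair", {
  set.seed(87)
  base <- rand_bases(300)
  shared <- sample.int(300, 30)          # 30 derived sites shared by A,B only
  ab <- mutate_at(base, shared)
  seqs <- c(A = mutate_at(ab, sample.int(300, 2)),
            B = mutate_at(ab, sample.int(300, 2)),
            C = mutate_at(base, sample.int(300, 4)),
            D = mutate_at(base, sample.int(300, 4)),
            E = mutate_at(base, sample.int(300, 4)))
  tr <- bootstrap_support(seqs, n_replicates = 200, seed = 88)
  # find the internal node joining exactly {A,B}
  pp <- ape::prop.part(tr)
  ab_clade <- which(vapply(pp, function(p)
    setequal(attr(pp, "labels")[p], c("A", "B")), logical(1)))
  expect_length(ab_clade, 1L)
  support <- tr$node.label[ab_clade]
  expect_gte(support, 99)
  expect_error(bootstrap_support(seqs, 0, seed = 1), "n_replicates")
  expect_error(bootstrap_support(c(A = "ACGT", B = "ACG"), 10, seed = 1),
               "equal-length")
})

test_that("bootstrap is deterministic for a fixed seed", {
  set.seed(89)
  base <- rand_bases(200)
  seqs <- setNames(vapply(1:5, function(k)
    mutate_at(base, sample.int(200, 6 * k)), character(1)), paste0("t", 1:5))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_newick(bootstrap_support(seqs, 50, seed = 42), f1)
  write_newick(bootstrap_support(seqs, 50, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
})
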