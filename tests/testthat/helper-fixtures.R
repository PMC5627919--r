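# Shared in-code fixtures for the test suite. Everything is generated at
# test time under fixed seeds; nothing is read from disk.

# random ACGT string
rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# substitute exactly k positions (given or sampled), never back to the old base
mutate_at <- function(bases, pos, to = NULL) {
  v <- strsplit(bases, "", fixed = TRUE)[[1]]
  for (i in seq_along(pos)) {
    p <- pos[i]
    v[p] <- if (!is.null(to)) to[i] else sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# a quality string of constant Phred q
qual_const <- function(q, n) strrep(intToUtf8(q + 33L), n)

# seq_records of identical reads of `bases` at constant Q30
reads_of <- function(bases, n, prefix = "r") {
  seq_records(sprintf("%s%04d", prefix, seq_len(n)), rep(bases, n),
              qual = qual_const(30L, nchar(bases)))
}

# one small reference set reused by several test files
tiny_reference <- function(seed = 11, n_species = 5, specimens = 2) {
  cfg <- sim_config(n_species = n_species, specimens_per_species = specimens,
                    seed = seed)
  simulate_reference_species(cfg)
}

# the published IUPAC complement table, used as an independent oracle
IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N", `-` = "-")
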