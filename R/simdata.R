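#' The degenerate COI amplicon primer pair used throughout
#'
#' The universal invertebrate COI fragment primers (forward
#' `GGWACWGGWTGAACWGTWTAYCCYCC`, reverse `TAAACTTCAGGGTGACCAAARAAYCA`)
#' flanking a ~313 bp fragment.
#'
#' @return list with `forward` and `reverse` IUPAC strings
#' @export
coi_primers <- function() {
  list(forward = "GGWACWGGWTGAACWGTWTAYCCYCC",
       reverse = "TAAACTTCAGGGTGACCAAARAAYCA")
}

#' Simulation configuration
#'
#' Defaults emulate the study regime: 313 bp coding barcodes (the COI
#' fragment length implied by the primer pair), ~2% intraspecific and
#' >=10% interspecific K2P divergence, per-specimen read sets with 1%
#' substitution error, bacterial contamination and two-parent chimeras, and
#' multi-sample communities.
#'
#' @param n_species number of species in the reference truth
#' @param specimens_per_species specimens (barcode variants) per species
#' @param barcode_length insert length in bases (>= 90); default 313
#' @param target_intraspecific_k2p pairwise divergence aimed for between
#'   conspecific specimen barcodes; default 0.02
#' @param min_interspecific_k2p minimum pairwise divergence between species
#'   barcodes (rejection-sampled); default 0.10
#' @param reads_per_specimen reads per specimen read set; default 500
#' @param substitution_error_rate per-base substitution error; default 0.01
#' @param contamination_fraction expected fraction of bacterial contaminant
#'   reads; default 0.10
#' @param chimera_fraction expected fraction of two-parent chimeric reads;
#'   default 0.05
#' @param n_samples community samples; default 12
#' @param reads_per_sample reads per community sample; default 600
#' @param n_decoys bacterial decoy templates; default 3
#' @param homopolymer_indel_rate per-homopolymer-run probability of a
#'   one-base expansion or contraction (the dominant indel mode of
#'   semiconductor sequencing); default 0 (substitution-only error model)
#' @param seed RNG seed (mandatory)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_species = 10L, specimens_per_species = 2L,
                       barcode_length = 313L,
                       target_intraspecific_k2p = 0.02,
                       min_interspecific_k2p = 0.10,
                       reads_per_specimen = 500L,
                       substitution_error_rate = 0.01,
                       contamination_fraction = 0.10,
                       chimera_fraction = 0.05,
                       n_samples = 12L, reads_per_sample = 600L,
                       n_decoys = 3L, homopolymer_indel_rate = 0,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  rates <- c(target_intraspecific_k2p = target_intraspecific_k2p,
             substitution_error_rate = substitution_error_rate,
             contamination_fraction = contamination_fraction,
             chimera_fraction = chimera_fraction,
             homopolymer_indel_rate = homopolymer_indel_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (contamination_fraction + chimera_fraction > 1)
    stop("contamination_fraction + chimera_fraction must not exceed 1",
         call. = FALSE)
  if (barcode_length < 90L) stop("barcode_length must be >= 90", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = as.integer(specimens_per_species),
                 barcode_length = as.integer(barcode_length),
                 target_intraspecific_k2p = target_intraspecific_k2p,
                 min_interspecific_k2p = min_interspecific_k2p,
                 reads_per_specimen = as.integer(reads_per_specimen),
                 substitution_error_rate = substitution_error_rate,
                 contamination_fraction = contamination_fraction,
                 chimera_fraction = chimera_fraction,
                 n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 n_decoys = as.integer(n_decoys),
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# codons that are not stops under the invertebrate mitochondrial code
# (table 5: only TAA and TAG terminate; TGA is Trp, AGA/AGG are Ser)
.nonstop_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG"))
})

# random frame-0 stop-free coding sequence of `len` bases
.random_coding <- function(len) {
  nc <- len %/% 3L
  rem <- len - 3L * nc
  paste0(paste(sample(.nonstop_codons, nc, replace = TRUE), collapse = ""),
         paste(sample(c("A", "C", "G", "T"), rem, replace = TRUE),
               collapse = ""))
}

# substitute `k` distinct positions, transition-biased 50/50, keeping frame
# 0 free of internal stops
.mutate_coding <- function(bases, k) {
  if (k == 0L) return(bases)
  v <- strsplit(bases, "", fixed = TRUE)[[1]]
  L <- length(v)
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  pos <- sample.int(L, min(k, L))
  for (p in pos) {
    old <- v[p]
    alts <- if (runif(1) < 0.5) transit[[old]]
            else sample(setdiff(c("A", "C", "G", "T"), c(old, transit[[old]])), 1)
    cand <- unique(c(alts, setdiff(c("A", "C", "G", "T"), old)))
    for (nb in cand) {
      v[p] <- nb
      cs <- ((p - 1L) %/% 3L) * 3L + 1L
      if (cs + 2L > L) break  # partial trailing codon cannot be a stop
      if (!(paste(v[cs:(cs + 2L)], collapse = "") %in% c("TAA", "TAG"))) break
      v[p] <- old  # this base would create a stop; try the next candidate
    }
  }
  paste(v, collapse = "")
}

#' Simulate a reference species set with screening panel and truth manifest
#'
#' Species barcodes are built codon-by-codon (invertebrate mitochondrial
#' code, no internal stops in frame 0) by mutating a common ancestor, and
#' rejection-sampled until every interspecific pairwise K2P distance
#' reaches `min_interspecific_k2p`. Each specimen gets a conspecific
#' variant placed so that pairwise intraspecific divergence lands near
#' `target_intraspecific_k2p`. Bacterial decoys are independent coding
#' sequences at least 30% amino-acid divergent from every target; the
#' screening panel is the frame-0 translations of targets
#' (`target_COI`) and decoys (`bacterial_COI`).
#'
#' @param cfg a [sim_config()]
#' @return list of class `sim_reference`: `species` (species_id, bases),
#'   `specimens` (specimen_id, species_id, bases), `decoys`, `panel`,
#'   `taxonomy`, `cfg`
#' @export
simulate_reference_species <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    L <- cfg$barcode_length
    ns <- cfg$n_species
    # each species sits ~0.75*min_inter from the ancestor, so pairs sit
    # ~1.5*min_inter apart before rejection sampling
    k_inter <- max(1L, round(0.75 * cfg$min_interspecific_k2p * L))
    ancestor <- .random_coding(L)
    species <- vapply(seq_len(ns), function(i) .mutate_coding(ancestor, k_inter),
                      character(1))
    names(species) <- sprintf("sp%02d", seq_len(ns))
    for (try in seq_len(50L)) {
      m <- k2p_matrix(species)
      m[is.na(m)] <- Inf
      diag(m) <- Inf
      bad <- which(apply(m, 1, min) < cfg$min_interspecific_k2p)
      if (!length(bad)) break
      if (try == 50L)
        stop("could not satisfy min_interspecific_k2p after 50 retries",
             call. = FALSE)
      for (b in bad)
        species[b] <- .mutate_coding(ancestor, k_inter)
    }

    k_intra <- round(cfg$target_intraspecific_k2p / 2 * L)
    specimens <- do.call(rbind, lapply(names(species), function(sp) {
      data.frame(
        specimen_id = sprintf("%s_ind%02d", sp, seq_len(cfg$specimens_per_species)),
        species_id = sp,
        bases = vapply(seq_len(cfg$specimens_per_species),
                       function(i) .mutate_coding(species[[sp]], k_intra),
                       character(1)),
        stringsAsFactors = FALSE)
    }))

    target_aa <- vapply(species, function(s) translate_dna(s, 0L, "5"),
                        character(1))
    decoys <- character(cfg$n_decoys)
    for (d in seq_len(cfg$n_decoys)) {
      for (try in seq_len(50L)) {
        cand <- .random_coding(L)
        aa <- translate_dna(cand, 0L, "5")
        ident <- vapply(target_aa, function(t) pairwise_identity(aa, t)$identity,
                        numeric(1))
        if (all(ident <= 70)) { decoys[d] <- cand; break }
        if (try == 50L)
          stop("could not generate a sufficiently divergent decoy", call. = FALSE)
      }
    }
    names(decoys) <- sprintf("decoy%02d", seq_len(cfg$n_decoys))

    pan <- panel(c(names(species), names(decoys)),
                 c(rep("target_COI", ns), rep("bacterial_COI", cfg$n_decoys)),
                 c(target_aa,
                   vapply(decoys, function(s) translate_dna(s, 0L, "5"),
                          character(1))))
    groups <- rep(c("Cladocera", "Copepoda", "Rotifera"), length.out = ns)
    taxonomy <- data.frame(
      ref_id = specimens$specimen_id,
      species = specimens$species_id,
      group = groups[match(specimens$species_id, names(species))],
      lineage = "",
      stringsAsFactors = FALSE)
    structure(list(species = data.frame(species_id = names(species),
                                        bases = unname(species),
                                        stringsAsFactors = FALSE),
                   specimens = specimens, decoys = decoys, panel = pan,
                   taxonomy = taxonomy, cfg = cfg),
              class = "sim_reference")
  })
}

# instantiate a degenerate primer for `m` reads (each degenerate position
# drawn uniformly from its IUPAC set, as in a synthesized oligo pool)
.instantiate_primer <- function(primer, m) {
  p <- strsplit(normalize_bases(primer), "", fixed = TRUE)[[1]]
  mat <- matrix(rep(p, each = m), nrow = m)
  for (j in seq_along(p)) {
    set <- .iupac_sets[[p[j]]]
    if (length(set) > 1L) mat[, j] <- sample(set, m, replace = TRUE)
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# apply per-base substitution errors to a vector of reads (the replacement
# base is uniform over the three alternatives, via a cyclic ACGT shift)
.add_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  for (L in unique(nchar(reads))) {
    idx <- which(nchar(reads) == L)
    n_err <- rbinom(length(idx), L, rate)
    tot <- sum(n_err)
    if (tot == 0L) next
    m <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE),
                       use.names = FALSE), ncol = L, byrow = TRUE)
    rows <- rep(seq_along(idx), n_err)
    pos <- unlist(lapply(n_err[n_err > 0L], function(k) sample.int(L, k)),
                  use.names = FALSE)
    cells <- cbind(rows, pos)
    old <- match(m[cells], c("A", "C", "G", "T"))
    hit <- !is.na(old)
    shift <- sample.int(3L, tot, replace = TRUE)
    m[cells[hit, , drop = FALSE]] <-
      c("A", "C", "G", "T")[((old[hit] - 1L + shift[hit]) %% 4L) + 1L]
    reads[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  reads
}

# one-base expansions/contractions of homopolymer runs (>= 2 identical
# bases), each run hit independently with probability `rate`
.add_homopolymer_indels <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  for (i in seq_along(reads)) {
    runs <- gregexpr("([ACGT])\\1+", reads[i])[[1]]
    if (runs[1] == -1L) next
    hit <- which(runif(length(runs)) < rate)
    if (!length(hit)) next
    v <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (j in rev(hit)) {   # right to left keeps positions valid
      pos <- runs[j]
      v <- if (runif(1) < 0.5) append(v, v[pos], after = pos) else v[-pos]
    }
    reads[i] <- paste(v, collapse = "")
  }
  reads
}

# primer-flank, orient half the reads in reverse, Q30 qualities
.package_reads <- function(inserts, ids, error_rate, indel_rate = 0) {
  m <- length(inserts)
  pr <- coi_primers()
  fwd <- .instantiate_primer(pr$forward, m)
  rev <- .instantiate_primer(pr$reverse, m)
  reads <- paste0(fwd, inserts, reverse_complement(rev))
  reads <- .add_errors(reads, error_rate)
  reads <- .add_homopolymer_indels(reads, indel_rate)
  flip <- runif(m) < 0.5
  reads[flip] <- reverse_complement(reads[flip])
  seq_records(ids, reads, qual = strrep("?", nchar(reads)))  # '?' = Q30
}

#' Simulate the read set of one specimen
#'
#' Reads are primer-flanked copies of the true barcode with per-base
#' substitution errors; a `contamination_fraction` of reads comes from
#' bacterial decoys and a `chimera_fraction` from single-crossover joins of
#' the barcode and a decoy (crossover uniform over the central 25-75% of
#' the insert, so each parent contributes an anchor segment). Half the
#' reads are emitted reverse-complemented; qualities are constant Q30.
#'
#' @param barcode the specimen's true (stop-free) barcode
#' @param cfg a [sim_config()]
#' @param decoys named character vector of contaminant templates
#' @param specimen_id id prefix for read names
#' @param seed RNG seed; defaults to `cfg$seed`
#' @return list of class `sim_readset`: `reads` (`seq_records`), `truth`
#'   (barcode, per-type counts, per-read type table)
#' @export
simulate_specimen_readset <- function(barcode, cfg, decoys,
                                      specimen_id = "specimen",
                                      seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), length(decoys) >= 1L)
  withr::with_seed(seed, {
    n <- cfg$reads_per_specimen
    type <- sample(c("target", "contaminant", "chimera"), n, replace = TRUE,
                   prob = c(1 - cfg$contamination_fraction - cfg$chimera_fraction,
                            cfg$contamination_fraction, cfg$chimera_fraction))
    L <- nchar(barcode)
    inserts <- character(n)
    inserts[type == "target"] <- barcode
    nc <- sum(type == "contaminant")
    if (nc) inserts[type == "contaminant"] <-
        decoys[sample.int(length(decoys), nc, replace = TRUE)]
    xi <- which(type == "chimera")
    crossover <- rep(NA_integer_, n)
    for (i in xi) {
      dk <- decoys[[sample.int(length(decoys), 1)]]
      k <- sample(seq(round(0.25 * L), round(0.75 * L)), 1)
      crossover[i] <- k
      inserts[i] <- if (runif(1) < 0.5)
        paste0(substr(barcode, 1, k), substr(dk, k + 1, nchar(dk)))
      else
        paste0(substr(dk, 1, k), substr(barcode, k + 1, L))
    }
    reads <- .package_reads(inserts, sprintf("%s_r%05d", specimen_id, seq_len(n)),
                            cfg$substitution_error_rate,
                            cfg$homopolymer_indel_rate)
    structure(list(reads = reads,
                   truth = list(barcode = barcode,
                                counts = table(factor(type, levels =
                                  c("target", "contaminant", "chimera"))),
                                per_read = data.frame(id = reads$id, type = type,
                                                      crossover = crossover,
                                                      stringsAsFactors = FALSE))),
              class = "sim_readset")
  })
}

#' Simulate a multi-sample community with ground truth
#'
#' Per species, an occupancy frequency is drawn uniformly on
#' \[0.15, 0.95\] and presence per sample is Bernoulli; present species
#' receive symmetric-Dirichlet relative abundances and reads are drawn
#' multinomially, then packaged with sequencing error like specimen reads.
#' The presence truth table doubles as the synthetic "morphology" survey
#' for the concordance module.
#'
#' @param ref a `sim_reference`
#' @param cfg a [sim_config()] (the community fields and error rate apply)
#' @param seed RNG seed; defaults to `cfg$seed`
#' @return list of class `sim_community`: `reads` (`seq_records` pooled
#'   over samples), `sample` (per-read sample label), `truth_presence`
#'   (species x sample logical), `truth_reads` (species x sample counts),
#'   `occupancy`
#' @export
simulate_community <- function(ref, cfg, seed = cfg$seed) {
  stopifnot(inherits(ref, "sim_reference"))
  withr::with_seed(seed, {
    sp <- ref$species$species_id
    ns <- length(sp)
    samples <- sprintf("S%02d", seq_len(cfg$n_samples))
    occupancy <- setNames(runif(ns, 0.15, 0.95), sp)
    presence <- matrix(runif(ns * cfg$n_samples) < occupancy,
                       nrow = ns, dimnames = list(sp, samples))
    reads_mat <- matrix(0L, ns, cfg$n_samples, dimnames = list(sp, samples))
    all_inserts <- character(0)
    all_samples <- character(0)
    all_species <- character(0)
    for (j in seq_len(cfg$n_samples)) {
      here <- which(presence[, j])
      if (!length(here)) next
      w <- rgamma(length(here), shape = 1)
      counts <- as.vector(rmultinom(1, cfg$reads_per_sample, w / sum(w)))
      reads_mat[here, j] <- counts
      all_inserts <- c(all_inserts, rep(ref$species$bases[here], counts))
      all_samples <- c(all_samples, rep(samples[j], sum(counts)))
      all_species <- c(all_species, rep(sp[here], counts))
    }
    reads <- .package_reads(all_inserts,
                            sprintf("com_r%06d", seq_along(all_inserts)),
                            cfg$substitution_error_rate,
                            cfg$homopolymer_indel_rate)
    structure(list(reads = reads, sample = all_samples,
                   truth_species = all_species,
                   truth_presence = presence, truth_reads = reads_mat,
                   occupancy = occupancy),
              class = "sim_community")
  })
}
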