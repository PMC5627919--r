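#' Transition/transversion site counts for an aligned pair
#'
#' Pairwise deletion: positions where either sequence carries a gap or a
#' non-ACGT symbol are excluded. A<->G and C<->T count as transitions, all
#' other differing ACGT pairs as transversions.
#'
#' @param a,b aligned sequences of equal length
#' @return list of class `site_counts`: `n_valid`, `n_transitions`,
#'   `n_transversions`, `P` (transition proportion), `Q` (transversion
#'   proportion)
#' @export
count_sites <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned (equal length)", call. = FALSE)
  x <- .base_codes(a)
  y <- .base_codes(b)
  valid <- !is.na(x) & !is.na(y)
  nv <- sum(valid)
  if (nv == 0L) stop("no comparable sites", call. = FALSE)
  diff <- valid & (x != y)
  ts <- sum(diff & (x %% 2L == y %% 2L), na.rm = TRUE)
  tv <- sum(diff, na.rm = TRUE) - ts
  structure(list(n_valid = nv, n_transitions = ts, n_transversions = tv,
                 P = ts / nv, Q = tv / nv),
            class = "site_counts")
}

# A=1 C=2 G=3 T=4 (purines odd, pyrimidines even), anything else NA
.base_codes <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

#' Kimura two-parameter distance
#'
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q)}
#' where P and Q are the transition and transversion proportions. When a
#' logarithm argument is non-positive the pair is saturated and an error of
#' class `k2p_saturation` is raised (matrix builders catch it and record
#' the pair as saturated).
#'
#' @param counts a `site_counts` object (or any list with `P` and `Q`)
#' @return substitutions per site (0 iff P == Q == 0)
#' @export
k2p_distance <- function(counts) {
  P <- counts$P
  Q <- counts$Q
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop(structure(class = c("k2p_saturation", "error", "condition"),
                   list(message = sprintf(
                          "K2P saturation: P=%.4f Q=%.4f leaves a non-positive log argument",
                          P, Q),
                        call = sys.call())))
  -0.5 * log(a1) - 0.25 * log(a2)
}

# K2P for one (possibly unequal-length) pair; global alignment when lengths
# differ; returns list(distance, saturated)
.k2p_pair <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    al <- pairwise_identity(a, b, keep_alignment = TRUE)
    a <- al$a_aln
    b <- al$b_aln
  }
  tryCatch(list(distance = k2p_distance(count_sites(a, b)), saturated = FALSE),
           k2p_saturation = function(e) list(distance = NA_real_, saturated = TRUE))
}

#' Pairwise K2P distance matrix
#'
#' Equal-length inputs are treated as the alignment; unequal-length pairs
#' are globally aligned first. Saturated pairs are `NA` in the matrix and
#' `TRUE` in the `"saturated"` attribute.
#'
#' @param seqs named character vector of sequences
#' @return symmetric matrix (substitutions per site, zero diagonal) with a
#'   logical `"saturated"` attribute of the same shape
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  labels <- names(seqs)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (n < 2L) { attr(d, "saturated") <- sat; return(d) }
  if (length(unique(nchar(seqs))) == 1L) {
    codes <- vapply(seqs, .base_codes, integer(nchar(seqs[[1]])))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      x <- codes[, i]; y <- codes[, j]
      valid <- !is.na(x) & !is.na(y)
      nv <- sum(valid)
      if (nv == 0L) stop(sprintf("no comparable sites between %s and %s",
                                 labels[i], labels[j]), call. = FALSE)
      diff <- valid & (x != y)
      ts <- sum(diff & (x %% 2L == y %% 2L), na.rm = TRUE)
      tv <- sum(diff, na.rm = TRUE) - ts
      r <- tryCatch(list(d = k2p_distance(list(P = ts / nv, Q = tv / nv)), s = FALSE),
                    k2p_saturation = function(e) list(d = NA_real_, s = TRUE))
      d[i, j] <- d[j, i] <- r$d
      sat[i, j] <- sat[j, i] <- r$s
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      r <- .k2p_pair(seqs[[i]], seqs[[j]])
      d[i, j] <- d[j, i] <- r$distance
      sat[i, j] <- sat[j, i] <- r$saturated
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Per-species intraspecific K2P divergence
#'
#' For every species with at least two sequences, the mean and maximum of
#' all pairwise K2P distances; species with a single sequence get `NA`.
#' Saturated pairs are excluded from the summaries and counted.
#'
#' @param db a `reference_db`
#' @return data frame: species, group, n_seqs, n_pairs, n_saturated,
#'   mean_k2p, max_k2p
#' @export
intraspecific_divergence <- function(db) {
  tax <- db$taxonomy
  species <- unique(tax$species[nzchar(tax$species)])
  rows <- lapply(species, function(sp) {
    ids <- tax$ref_id[tax$species == sp]
    grp <- tax$group[tax$species == sp][1]
    k <- length(ids)
    if (k < 2L)
      return(data.frame(species = sp, group = grp, n_seqs = k, n_pairs = 0L,
                        n_saturated = 0L, mean_k2p = NA_real_,
                        max_k2p = NA_real_, stringsAsFactors = FALSE))
    m <- k2p_matrix(db$seq[ids])
    v <- m[upper.tri(m)]
    sat <- sum(is.na(v))
    if (sat > 0L)
      warning(sprintf("%d saturated pair(s) excluded for species %s", sat, sp))
    v <- v[!is.na(v)]
    data.frame(species = sp, group = grp, n_seqs = k,
               n_pairs = length(v) + sat, n_saturated = sat,
               mean_k2p = if (length(v)) mean(v) else NA_real_,
               max_k2p = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Barcode-gap audit: which species pairs are unresolved?
#'
#' A species pair is unresolved iff the minimum interspecific K2P between
#' them does not exceed the maximum intraspecific K2P within either species
#' (no barcode gap) — identical barcodes across species are the limiting
#' case. Saturated interspecific pairs are treated as resolvable distance.
#'
#' @param db a `reference_db` with at least two species
#' @return data frame of unresolved pairs: species_a, species_b,
#'   min_interspecific, max_intraspecific
#' @export
discrimination_check <- function(db) {
  tax <- db$taxonomy
  species <- unique(tax$species[nzchar(tax$species)])
  if (length(species) < 2L)
    stop("discrimination_check needs at least two species", call. = FALSE)
  m <- k2p_matrix(db$seq)
  sp_of <- tax$species[match(names(db$seq), tax$ref_id)]
  max_intra <- vapply(species, function(sp) {
    i <- which(sp_of == sp)
    if (length(i) < 2L) return(0)
    v <- m[i, i][upper.tri(m[i, i])]
    v <- v[!is.na(v)]
    if (length(v)) max(v) else 0
  }, numeric(1))
  out <- list()
  for (i in seq_len(length(species) - 1L)) for (j in (i + 1L):length(species)) {
    ii <- which(sp_of == species[i]); jj <- which(sp_of == species[j])
    inter <- m[ii, jj, drop = FALSE]
    inter <- inter[!is.na(inter)]
    if (!length(inter)) next  # all saturated: clearly resolved
    gap_fail <- min(inter) <= max(max_intra[i], max_intra[j])
    if (gap_fail)
      out[[length(out) + 1L]] <- data.frame(
        species_a = species[i], species_b = species[j],
        min_interspecific = min(inter),
        max_intraspecific = max(max_intra[i], max_intra[j]),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(species_a = character(0), species_b = character(0),
                      min_interspecific = numeric(0),
                      max_intraspecific = numeric(0)))
  do.call(rbind, out)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion. For an additive input
#' matrix the tree's path-length matrix reproduces the input. Negative
#' estimated branch lengths are clamped to zero; the summed deficit is
#' attached as attribute `"negative_deficit"`. The tree is returned
#' unrooted (trifurcating basal node) as an [ape::read.tree()] `phylo`.
#'
#' @param m symmetric distance matrix with labeled dimnames, no `NA`
#'   (saturated) entries
#' @return a `phylo` object
#' @export
nj_tree <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  if (anyNA(m)) stop("distance matrix contains saturated (NA) entries",
                     call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  deficit <- 0
  br <- function(x) {
    if (x < 0) { deficit <<- deficit - x; x <- 0 }
    sprintf("%.17g", x)
  }
  if (n == 2L) {
    h <- m[1, 2] / 2
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                        labels[1], br(h), labels[2], br(h)))
    attr(tr, "negative_deficit") <- deficit
    return(tr)
  }
  node <- as.list(labels)   # newick fragment per active node
  D <- m
  active <- seq_len(n)
  while (length(active) > 3L) {
    r <- length(active)
    Da <- D[active, active]
    rs <- rowSums(Da)
    Qm <- (r - 2) * Da - outer(rs, rs, "+")
    diag(Qm) <- Inf
    k <- which.min(Qm)            # ties: first in column-major order
    i <- (k - 1L) %% r + 1L
    j <- (k - 1L) %/% r + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- Da[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    ai <- active[i]; aj <- active[j]
    newdist <- (Da[i, ] + Da[j, ] - dij) / 2
    # grow matrices by one node
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    rest <- active[-c(i, j)]
    D[u, rest] <- D[rest, u] <- newdist[-c(i, j)]
    node[[u]] <- sprintf("(%s:%s,%s:%s)",
                         node[[ai]], br(li), node[[aj]], br(lj))
    active <- c(rest, u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  dab <- D[a, b]; dac <- D[a, c3]; dbc <- D[b, c3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[[a]], br(la), node[[b]], br(lb), node[[c3]], br(lc))
  tr <- ape::read.tree(text = txt)
  attr(tr, "negative_deficit") <- deficit
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Alignment columns are resampled with replacement; each replicate gets a
#' K2P matrix and NJ tree; the support of each internal edge of the
#' full-data tree is the percentage of completed replicates containing the
#' same bipartition. Replicates in which any pair saturates (or loses all
#' comparable sites) are skipped and excluded from the denominator.
#'
#' @param seqs named character vector, all sequences equal length (treated
#'   as the alignment)
#' @param n_replicates bootstrap replicates; default 1000
#' @param seed RNG seed (mandatory: resampling must be reproducible)
#' @return the full-data `phylo` with `node.label` holding percent support;
#'   attributes `"completed"` and `"skipped"` count replicates
#' @export
bootstrap_support <- function(seqs, n_replicates = 1000L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("bootstrap requires equal-length (aligned) sequences", call. = FALSE)
  ref <- nj_tree(k2p_matrix(seqs))
  L <- nchar(seqs[[1]])
  trees <- list()
  skipped <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rs <- vapply(seqs, function(s)
        paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = ""),
        character(1))
      tr <- tryCatch(nj_tree(k2p_matrix(rs)), error = function(e) NULL)
      if (is.null(tr)) skipped <- skipped + 1L
      else trees[[length(trees) + 1L]] <- tr
    }
  })
  if (!length(trees)) stop("all bootstrap replicates saturated", call. = FALSE)
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- round(100 * counts / length(trees), 1)
  attr(ref, "completed") <- length(trees)
  attr(ref, "skipped") <- skipped
  ref
}

#' Write a tree as Newick with supports as internal node labels
#' @param tree a `phylo`
#' @param path output path
#' @param digits branch-length precision; default 6
#' @export
write_newick <- function(tree, path, digits = 6L) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Write a distance matrix as TSV (labels in the first row and column)
#' @param m matrix with dimnames
#' @param path output path
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
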