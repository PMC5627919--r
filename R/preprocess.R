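#' Filtering parameters for read pre-treatment
#'
#' @param max_primer_mismatches maximum IUPAC-aware mismatches tolerated in
#'   the forward primer (reads beyond this in both orientations are
#'   discarded); default 2
#' @param min_length minimum read length in bases after primer trimming;
#'   reads strictly shorter are removed; default 200
#' @param max_expected_errors maximum per-read expected error count
#'   \eqn{\sum 10^{-q/10}}; default 1.0
#' @param min_mean_quality minimum mean Phred score; default 20
#' @return a `filter_params` list
#' @export
filter_params <- function(max_primer_mismatches = 2L, min_length = 200L,
                          max_expected_errors = 1.0, min_mean_quality = 20) {
  stopifnot(max_primer_mismatches >= 0, min_length >= 1,
            max_expected_errors >= 0, min_mean_quality >= 0)
  structure(list(max_primer_mismatches = as.integer(max_primer_mismatches),
                 min_length = as.integer(min_length),
                 max_expected_errors = max_expected_errors,
                 min_mean_quality = min_mean_quality),
            class = "filter_params")
}

#' Quality-based whole-read accept/reject
#'
#' A read is discarded iff its expected error count
#' \eqn{\sum_i 10^{-q_i/10}} exceeds `max_expected_errors` or its mean Phred
#' score falls below `min_mean_quality`. No quality trimming is performed.
#'
#' @param records `seq_records` with qualities present
#' @param params a [filter_params()] list
#' @return logical vector, `TRUE` = keep
#' @export
quality_filter <- function(records, params = filter_params()) {
  if (any(is.na(records$qual)))
    stop("quality_filter requires per-base qualities on every record",
         call. = FALSE)
  scores <- phred_scores(records$qual)
  ee <- vapply(scores, function(q) sum(10^(-q / 10)), numeric(1))
  mq <- vapply(scores, function(q) if (length(q)) mean(q) else 0, numeric(1))
  ee <= params$max_expected_errors & mq >= params$min_mean_quality
}

# vectorized IUPAC mismatch count of fixed-length windows vs one primer;
# windows shorter than the primer get Inf
.primer_mismatch_vec <- function(windows, primer) {
  plen <- nchar(primer)
  out <- rep(Inf, length(windows))
  ok <- nchar(windows) == plen
  if (!any(ok)) return(out)
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  w <- matrix(unlist(strsplit(windows[ok], "", fixed = TRUE), use.names = FALSE),
              ncol = plen, byrow = TRUE)
  mm <- !.iupac_intersects[cbind(as.vector(w), rep(p, each = nrow(w)))]
  out[ok] <- rowSums(matrix(mm, ncol = plen))
  out
}

#' Locate, orient by and trim amplicon primers
#'
#' The forward primer is sought at the 5' end of each read and of its
#' reverse complement, with an end-anchored slack window of `slack` bases;
#' the orientation with fewer forward-primer mismatches wins (ties go to the
#' forward orientation) and the read is re-oriented to the forward strand.
#' The forward primer (and any slack bases before it) is trimmed; if the
#' reverse complement of the reverse primer is found within
#' `max_mismatches` at the 3' end it is trimmed as well. A read is rejected
#' iff the forward primer exceeds `max_mismatches` in both orientations.
#'
#' @param records `seq_records`
#' @param forward,reverse IUPAC primer strings (as synthesized, 5'->3')
#' @param max_mismatches maximum tolerated forward-primer mismatches
#'   (IUPAC-aware); default 2
#' @param slack how far from the read end the primer may start; default 2
#' @return list with `records` (kept reads, trimmed and forward-oriented,
#'   with an `orientation` column) and `log` (one row per input read:
#'   id, fate, reason)
#' @export
locate_and_trim_primers <- function(records, forward, reverse,
                                    max_mismatches = 2L, slack = 2L) {
  forward <- normalize_bases(forward)
  reverse <- normalize_bases(reverse)
  n <- nrow(records)
  if (n == 0L)
    return(list(records = records,
                log = data.frame(id = character(0), fate = character(0),
                                 reason = character(0))))
  plen <- nchar(forward)
  bases <- records$bases
  rc <- reverse_complement(bases)

  best_over_offsets <- function(seqs) {
    mm <- rep(Inf, length(seqs)); off <- rep(NA_integer_, length(seqs))
    for (o in 0:slack) {
      m <- .primer_mismatch_vec(substr(seqs, o + 1L, o + plen), forward)
      better <- m < mm
      mm[better] <- m[better]; off[better] <- o
    }
    list(mm = mm, off = off)
  }
  fw <- best_over_offsets(bases)
  rv <- best_over_offsets(rc)

  use_rev <- rv$mm < fw$mm
  mm <- ifelse(use_rev, rv$mm, fw$mm)
  off <- ifelse(use_rev, rv$off, fw$off)
  keep <- mm <= max_mismatches

  oriented <- ifelse(use_rev, rc, bases)
  qual <- records$qual
  if (any(use_rev & !is.na(qual))) {
    i <- which(use_rev & !is.na(qual))
    qual[i] <- vapply(qual[i],
                      function(q) intToUtf8(rev(utf8ToInt(q))), character(1))
  }
  # trim 5': slack bases + forward primer
  from <- off + plen + 1L
  trimmed <- substr(oriented, from, nchar(oriented))
  qual <- ifelse(is.na(qual), qual, substr(qual, from, nchar(oriented)))

  # 3': reverse complement of the reverse primer, optional trim
  rp <- reverse_complement(reverse)
  rplen <- nchar(rp)
  L <- nchar(trimmed)
  end_mm <- rep(Inf, n); end_start <- rep(NA_integer_, n)
  for (o in 0:slack) {
    wnd <- substr(trimmed, L - o - rplen + 1L, L - o)
    m <- .primer_mismatch_vec(wnd, rp)
    better <- m < end_mm
    end_mm[better] <- m[better]; end_start[better] <- (L - o - rplen + 1L)[better]
  }
  has_rp <- end_mm <= max_mismatches
  to <- ifelse(has_rp, end_start - 1L, L)
  trimmed <- substr(trimmed, 1L, to)
  qual <- ifelse(is.na(qual), qual, substr(qual, 1L, to))

  fate <- ifelse(keep, "kept", "rejected")
  reason <- ifelse(keep, "", sprintf("forward primer mismatches %s > %d",
                                     ifelse(is.finite(mm), mm, "NA"),
                                     max_mismatches))
  out <- records[keep, , drop = FALSE]
  out$bases <- trimmed[keep]
  out$qual <- qual[keep]
  out$orientation <- ifelse(use_rev[keep], "reverse", "forward")
  rownames(out) <- NULL
  list(records = out,
       log = data.frame(id = records$id, fate = fate, reason = reason,
                        stringsAsFactors = FALSE))
}

#' Remove short reads
#' @param records `seq_records`
#' @param min_length minimum length kept (reads strictly shorter removed)
#' @return the retained records
#' @export
length_filter <- function(records, min_length = 200L) {
  stopifnot(min_length >= 1)
  out <- records[nchar(records$bases) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dereplicate reads into unique sequences with abundances
#'
#' Identity is exact string equality. Output is sorted by abundance
#' descending, ties broken lexicographically by sequence, so downstream
#' greedy clustering is deterministic.
#'
#' @param records `seq_records` or a character vector of sequences
#' @param sample_labels optional per-read sample labels; when given, a
#'   per-sample count matrix is attached
#' @return a `derep` list: `bases`, `abundance`, and optionally `samples`
#'   (uniques x samples count matrix)
#' @export
dereplicate <- function(records, sample_labels = NULL) {
  bases <- if (is.character(records)) records else records$bases
  if (length(bases) == 0L)
    return(structure(list(bases = character(0), abundance = integer(0)),
                     class = "derep"))
  tab <- table(bases)
  uniq <- names(tab)
  ab <- as.integer(tab)
  ord <- order(-ab, uniq, method = "radix")
  out <- list(bases = uniq[ord], abundance = ab[ord])
  if (!is.null(sample_labels)) {
    stopifnot(length(sample_labels) == length(bases))
    cnt <- table(factor(bases, levels = out$bases), sample_labels)
    m <- matrix(as.integer(cnt), nrow = length(out$bases),
                dimnames = list(NULL, colnames(cnt)))
    out$samples <- m
  }
  structure(out, class = "derep")
}

#' Subset a derep object
#' @param x a `derep` object
#' @param i index vector of uniques to keep
#' @return the subset, same class
#' @export
derep_subset <- function(x, i) {
  out <- list(bases = x$bases[i], abundance = x$abundance[i])
  if (!is.null(x$samples))
    out$samples <- x$samples[i, , drop = FALSE]
  structure(out, class = "derep")
}

#' De-novo two-parent chimera detection
#'
#' Each unique sequence (the query) is tested against candidate parents
#' that are at least `min_fold` times more abundant. The query is flagged
#' as chimeric iff some single-crossover concatenation of two parents
#' matches it better than any single parent does, with an identity gain of
#' at least `min_divergence` percentage points, and each parent contributes
#' at least `min_segment` matching positions to its side of the crossover.
#' This is the core two-parent/abundance-skew model of de-novo chimera
#' detectors; the candidate-parent set is capped at the `max_parents` most
#' abundant eligible uniques to keep the pair scan tractable. A chimera
#' model must also explain the query: the two-parent identity has to reach
#' `min_model_identity`, the same tolerance used to cluster reads — without
#' it, any unrelated query (e.g. a co-amplified contaminant) picks up a
#' spurious few-point "gain" from the best random crossover.
#'
#' @param uniques a `derep` object (abundance-sorted)
#' @param min_divergence minimum identity gain (percentage points) of the
#'   two-parent model over the best single parent; default 1
#' @param min_segment minimum matching positions each parent must
#'   contribute; default 30
#' @param min_fold abundance skew required of a parent; default 2
#' @param max_parents cap on candidate parents per query; default 8
#' @param min_model_identity minimum percent identity of the two-parent
#'   model to the query; default 97
#' @return data frame with one row per unique: `flagged`, `parent_a`,
#'   `parent_b` (indices into `uniques`), `crossover` (last query position
#'   taken from parent A), `single_identity`, `two_parent_identity`
#' @export
detect_chimeras <- function(uniques, min_divergence = 1, min_segment = 30L,
                            min_fold = 2, max_parents = 8L,
                            min_model_identity = 97) {
  n <- length(uniques$bases)
  res <- data.frame(flagged = logical(n), parent_a = NA_integer_,
                    parent_b = NA_integer_, crossover = NA_integer_,
                    single_identity = NA_real_, two_parent_identity = NA_real_)
  if (n < 3L) return(res)
  ab <- uniques$abundance
  for (a_class in sort(unique(ab))) {
    parents <- which(ab >= min_fold * a_class)
    if (length(parents) < 2L) next
    parents <- parents[seq_len(min(length(parents), max_parents))]
    queries <- which(ab == a_class)
    queries <- setdiff(queries, parents)
    if (!length(queries)) next
    scan <- .chimera_scan(uniques$bases, queries, parents,
                          min_divergence, min_segment, min_model_identity)
    res[queries, ] <- scan
  }
  res
}

# score queries against ordered parent pairs; returns a data frame aligned
# with `queries`. Equal-length sets (the common case: same-locus amplicons)
# run in compiled code over gap-free profiles; mixed lengths fall back to
# per-pair global alignment profiles in query coordinates.
.chimera_scan <- function(bases, queries, parents, min_divergence, min_segment,
                          min_model_identity = 97) {
  nq <- length(queries); np <- length(parents)
  qlen <- nchar(bases[queries])
  if (length(unique(nchar(bases[c(queries, parents)]))) == 1L) {
    m <- .chimera_scan_cpp(bases[queries], bases[parents], min_segment)
    single_best <- m[, "single"]
    best_val <- ifelse(m[, "two"] < 0, -Inf, m[, "two"])
    best_a <- as.integer(m[, "parent_a"])
    best_b <- as.integer(m[, "parent_b"])
    crossover <- as.integer(m[, "crossover"])
  } else {
    L <- max(qlen)
    cum <- vector("list", np)    # each: nq x (L+1), col 1 = 0 matches
    for (p in seq_len(np)) {
      mm <- matrix(0L, nq, L)
      for (qi in seq_len(nq)) {
        prof <- .match_profile(bases[queries[qi]], bases[parents[p]])
        mm[qi, seq_along(prof)] <- prof
      }
      cum[[p]] <- cbind(0L, matrix(t(apply(mm, 1L, cumsum)), nrow = nq))
    }
    tot <- matrix(vapply(seq_len(np), function(p) cum[[p]][, L + 1L],
                         numeric(nq)), nrow = nq)
    single_best <- apply(tot, 1L, max)
    best_val <- rep(-Inf, nq)
    best_a <- best_b <- rep(NA_integer_, nq)
    for (a in seq_len(np)) {
      ca <- cum[[a]]
      for (b in seq_len(np)) {
        if (a == b) next
        sb <- tot[, b] - cum[[b]]         # suffix matches from parent b
        comb <- ca + sb                   # nq x (L+1)
        comb[ca < min_segment | sb < min_segment] <- -Inf
        v <- apply(comb, 1L, max)
        better <- v > best_val
        best_val[better] <- v[better]
        best_a[better] <- a; best_b[better] <- b
      }
    }
    crossover <- rep(NA_integer_, nq)
    for (qi in which(is.finite(best_val))) {
      ca <- cum[[best_a[qi]]][qi, ]
      sb <- tot[qi, best_b[qi]] - cum[[best_b[qi]]][qi, ]
      comb <- ca + sb
      comb[ca < min_segment | sb < min_segment] <- -Inf
      # the optimum is a plateau between flanking parent differences;
      # report its midpoint
      ks <- which(comb == max(comb))
      crossover[qi] <- as.integer(round(mean(range(ks)))) - 1L
    }
  }
  single_identity <- 100 * single_best / qlen
  two_identity <- 100 * best_val / qlen
  flagged <- is.finite(two_identity) &
    (two_identity - single_identity) >= min_divergence &
    two_identity >= min_model_identity
  data.frame(flagged = flagged,
             parent_a = ifelse(flagged, parents[best_a], NA_integer_),
             parent_b = ifelse(flagged, parents[best_b], NA_integer_),
             crossover = ifelse(flagged, crossover, NA_integer_),
             single_identity = single_identity,
             two_parent_identity = ifelse(is.finite(two_identity),
                                          two_identity, NA_real_))
}

#' Full read pre-treatment: quality, primer, length, dereplication, chimera
#'
#' Applies the stages in the fixed order quality -> primer
#' orientation/trimming -> length -> dereplication -> de-novo chimera
#' detection, and returns the non-chimeric unique sequences together with a
#' per-read fate log.
#'
#' @param records `seq_records` with qualities
#' @param forward,reverse primer strings
#' @param params a [filter_params()] list
#' @param sample_labels optional per-read sample labels (carried through
#'   dereplication)
#' @return list: `uniques` (non-chimeric `derep`), `chimeras` (the
#'   [detect_chimeras()] table over all uniques), `log` (read id, fate,
#'   reason), `n_input`, `n_retained` (reads surviving all stages,
#'   chimeric uniques excluded)
#' @export
preprocess_reads <- function(records, forward, reverse,
                             params = filter_params(), sample_labels = NULL) {
  n_input <- nrow(records)
  log <- data.frame(id = records$id, fate = "kept", reason = "",
                    stringsAsFactors = FALSE)
  rownames(log) <- records$id

  qok <- quality_filter(records, params)
  log[records$id[!qok], "fate"] <- "rejected"
  log[records$id[!qok], "reason"] <- "low quality"
  records <- records[qok, , drop = FALSE]
  if (!is.null(sample_labels)) sample_labels <- sample_labels[qok]

  pr <- locate_and_trim_primers(records, forward, reverse,
                                params$max_primer_mismatches)
  rej <- pr$log$fate == "rejected"
  log[pr$log$id[rej], "fate"] <- "rejected"
  log[pr$log$id[rej], "reason"] <- pr$log$reason[rej]
  if (!is.null(sample_labels)) sample_labels <- sample_labels[!rej]
  records <- pr$records

  short <- nchar(records$bases) < params$min_length
  log[records$id[short], "fate"] <- "rejected"
  log[records$id[short], "reason"] <- sprintf("short read (< %d bp)",
                                              params$min_length)
  records <- records[!short, , drop = FALSE]
  if (!is.null(sample_labels)) sample_labels <- sample_labels[!short]

  uniques <- dereplicate(records, sample_labels)
  chim <- detect_chimeras(uniques)
  if (any(chim$flagged)) {
    flagged_bases <- uniques$bases[chim$flagged]
    hit <- records$id[records$bases %in% flagged_bases]
    log[hit, "fate"] <- "rejected"
    log[hit, "reason"] <- "chimeric"
  }
  keep <- derep_subset(uniques, which(!chim$flagged))
  rownames(log) <- NULL
  list(uniques = keep, chimeras = chim, log = log,
       n_input = n_input, n_retained = sum(keep$abundance))
}
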