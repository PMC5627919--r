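#' Pairwise global alignment with the package-wide identity definition
#'
#' All identity comparisons in the pipeline (read clustering, chimera parent
#' scoring, amino-acid panel screening, OTU taxonomic assignment) share one
#' definition: global (Needleman-Wunsch) alignment with match +1, mismatch
#' -1, gap open -2, gap extension -1; identity = matches / aligned columns
#' after terminal gap columns are stripped. `alignment_length` below is that
#' column count.
#'
#' @param a,b sequences (nucleotide or amino acid; compared by exact
#'   character equality)
#' @param keep_alignment return the two gapped alignment strings as well
#' @return list with `identity` (percent), `matches`, `alignment_length`,
#'   `score`, and if requested `a_aln`/`b_aln`
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA")$identity  # 87.5
pairwise_identity <- function(a, b, keep_alignment = FALSE) {
  r <- .nw_align_cpp(a, b, keep_alignment)
  out <- list(identity = r$identity, matches = r$matches,
              alignment_length = r$columns, score = r$score)
  if (keep_alignment) {
    out$a_aln <- r$a_aln
    out$b_aln <- r$b_aln
  }
  out
}

#' Align many sequences against one subject
#' @param seqs character vector
#' @param subject single sequence
#' @return matrix with columns identity, matches, columns, score (one row
#'   per element of `seqs`)
#' @keywords internal
pairwise_identity_many <- function(seqs, subject) {
  .nw_batch_cpp(seqs, subject)
}

# join decision for greedy clustering: is identity >= threshold?
# Equal-length pairs whose ungapped identity already clears both the
# threshold and 90% are accepted without the DP (at that similarity the
# gap-free alignment is the score optimum, so the answer is exact), and
# pairs more than 20 points below the threshold are rejected without it
# (overturning that would need a long compensating indel shift, which
# substitution-dominated amplicon reads do not produce). The gray zone and
# all unequal-length pairs run the full global alignment.
.identity_at_least <- function(a, b, threshold) {
  h <- .hamming_identity_cpp(a, b)
  if (h >= max(threshold, 90)) return(TRUE)
  if (h >= 0 && h < threshold - 20) return(FALSE)
  .nw_align_cpp(a, b, FALSE)$identity >= threshold
}

# per-query-position match profile of parent against query (1 = query base
# aligned to an identical parent base); fast path for equal length assumes
# the gap-free alignment, which is optimal under this scoring whenever
# the sequences are reasonably similar
.match_profile <- function(query, parent) {
  if (nchar(query) == nchar(parent)) {
    as.integer(strsplit(query, "", fixed = TRUE)[[1]] ==
               strsplit(parent, "", fixed = TRUE)[[1]])
  } else {
    .nw_profile_cpp(query, parent)
  }
}
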