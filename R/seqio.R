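#' @section Sequence records:
#' Reads and barcodes are carried as plain data frames of class
#' `"seq_records"` with columns `id`, `desc`, `bases` and `qual` (`qual` is
#' the raw Phred+33 string, or `NA` for FASTA-derived records). Bases are
#' upper-case IUPAC nucleotides; `U` is normalized to `T` on input.
#' @name seqio
#' @keywords internal
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), `-` = character(0)
)

# 16x16 logical: do the IUPAC sets of two symbols intersect?
.iupac_intersects <- local({
  m <- matrix(FALSE, 16L, 16L, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (x in IUPAC_CHARS) for (y in IUPAC_CHARS)
    m[x, y] <- length(intersect(.iupac_sets[[x]], .iupac_sets[[y]])) > 0L
  m
})

#' Normalize a nucleotide string to upper-case IUPAC (U -> T)
#' @param bases character vector of nucleotide strings
#' @return normalized character vector
#' @keywords internal
normalize_bases <- function(bases) {
  bases <- chartr("u", "U", toupper(bases))
  chartr("U", "T", bases)
}

.validate_bases <- function(bases, what = "bases") {
  bad <- grepl(sprintf("[^%s]", paste(c("ACGTRYSWKMBDHVN", "\\-"), collapse = "")),
               bases)
  if (any(bad))
    stop(sprintf("%s contain non-IUPAC characters (first offender: record %d)",
                 what, which(bad)[1]), call. = FALSE)
  invisible(bases)
}

#' Construct a set of sequence records
#'
#' @param id character vector of record identifiers (unique)
#' @param bases character vector of IUPAC nucleotide strings
#' @param desc optional descriptions
#' @param qual optional Phred+33 quality strings (same lengths as `bases`)
#' @return a data frame of class `seq_records`
#' @export
seq_records <- function(id, bases, desc = "", qual = NA_character_) {
  id <- as.character(id)
  bases <- normalize_bases(as.character(bases))
  .validate_bases(bases)
  if (anyDuplicated(id))
    stop("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "),
         call. = FALSE)
  desc <- rep_len(as.character(desc), length(id))
  qual <- rep_len(as.character(qual), length(id))
  has_q <- !is.na(qual)
  if (any(has_q & nchar(qual) != nchar(bases)))
    stop("quality string length differs from sequence length (record ",
         which(has_q & nchar(qual) != nchar(bases))[1], ")", call. = FALSE)
  if (any(has_q)) .validate_phred33(qual[has_q])
  out <- data.frame(id = id, desc = desc, bases = bases, qual = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

.validate_phred33 <- function(qual) {
  codes <- utf8ToInt(paste(qual, collapse = ""))
  if (length(codes) && (min(codes) < 33L || max(codes) > 126L))
    stop("quality characters outside the Phred+33 printable range [!, ~]; ",
         "Phred+64 input is not supported", call. = FALSE)
  invisible(qual)
}

#' Decode Phred+33 quality strings to integer scores
#' @param qual character vector of quality strings
#' @return list of integer vectors (Phred scores)
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' Strict parser for the 4-line FASTQ dialect: any structural defect is
#' reported with the 1-based line number of the offending line. Quality
#' characters outside `[!, ~]` are rejected (the encoding is fixed to
#' Phred+33; Phred+64 input errors rather than being guessed at).
#'
#' @param path path to a FASTQ file
#' @return a `seq_records` data frame, input order preserved
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(seq_records(character(0), character(0)))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at line %d in '%s'",
                 (length(lines) %/% 4L) * 4L + 1L, path), call. = FALSE)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: header must start with '@'",
                 (bad[1] - 1L) * 4L + 1L), call. = FALSE)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: separator must start with '+'",
                 (bad[1] - 1L) * 4L + 3L), call. = FALSE)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: quality length %d differs from sequence length %d",
                 (bad[1] - 1L) * 4L + 4L, nchar(qual[bad[1]]), nchar(seq[bad[1]])),
         call. = FALSE)
  id_desc <- sub("^@", "", hdr)
  id <- sub("[ \t].*$", "", id_desc)
  desc <- ifelse(grepl("[ \t]", id_desc), sub("^[^ \t]+[ \t]+", "", id_desc), "")
  seq_records(id, seq, desc, qual)
}

#' Write sequence records as 4-line FASTQ (Phred+33)
#' @param records a `seq_records` data frame with qualities present
#' @param path output path
#' @export
write_fastq <- function(records, path) {
  if (any(is.na(records$qual)))
    stop("records without qualities cannot be written as FASTQ", call. = FALSE)
  hdr <- ifelse(nzchar(records$desc),
                paste0("@", records$id, " ", records$desc),
                paste0("@", records$id))
  writeLines(rbind(hdr, records$bases, "+", records$qual), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Headers of the form `id;tax=k:...,p:...;` (a common annotated-FASTA
#' dialect) are recognized: the `tax=` payload is stripped from the id and
#' kept in the `desc` column.
#'
#' @param path path to a FASTA file
#' @return a `seq_records` data frame (qualities `NA`)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  full <- names(set)
  id <- sub("[ \t].*$", "", full)
  desc <- ifelse(grepl("[ \t]", full), sub("^[^ \t]+[ \t]+", "", full), "")
  tax <- grepl(";tax=", id, fixed = TRUE)
  if (any(tax)) {
    at <- regexpr(";tax=", id[tax], fixed = TRUE)
    payload <- substring(id[tax], at + 1L)
    desc[tax] <- paste0(payload,
                        ifelse(nzchar(desc[tax]), paste0(" ", desc[tax]), ""))
    id[tax] <- substring(id[tax], 1L, at - 1L)
  }
  seq_records(id, as.character(set), desc)
}

#' Write sequences as FASTA, wrapped at 80 columns
#' @param records a `seq_records` data frame, or a named character vector
#' @param path output path
#' @export
write_fasta <- function(records, path) {
  if (is.character(records))
    records <- seq_records(names(records), unname(records))
  set <- Biostrings::DNAStringSet(records$bases)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Reverse-complement IUPAC nucleotide strings
#'
#' Degenerate codes map through the IUPAC complement table (R<->Y, W<->W,
#' S<->S, K<->M, B<->V, D<->H, N<->N); gaps are preserved.
#'
#' @param bases character vector of IUPAC strings
#' @return character vector of reverse complements
#' @export
reverse_complement <- function(bases) {
  bases <- normalize_bases(bases)
  .validate_bases(bases)
  empty <- !nzchar(bases)
  out <- bases
  if (any(!empty))
    out[!empty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(bases[!empty])))
  out
}

#' Count mismatches between a read window and a (degenerate) primer
#'
#' A position matches iff the IUPAC sets of the two symbols intersect, so a
#' read `A` matches primer `W` but not primer `Y`, and `N` matches anything.
#'
#' @param window read substring, same length as `primer`
#' @param primer IUPAC primer string
#' @return integer count of non-matching positions
#' @export
count_primer_mismatches <- function(window, primer) {
  window <- normalize_bases(window)
  primer <- normalize_bases(primer)
  if (nchar(window) != nchar(primer))
    stop("window and primer must have equal length", call. = FALSE)
  if (!nzchar(primer)) return(0L)
  .validate_bases(c(window, primer))
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  sum(!.iupac_intersects[cbind(w, p)])
}

#' Read a taxonomy table
#'
#' Tab-separated with header `ref_id  species  group  lineage`; `lineage` is
#' a semicolon-joined rank list (kingdom to species, missing ranks allowed)
#' and may be empty.
#'
#' @param path path to the TSV
#' @return data frame with columns ref_id, species, group, lineage
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tax <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("ref_id", "species", "group", "lineage")
  miss <- setdiff(need, names(tax))
  if (length(miss))
    stop("taxonomy table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tax$ref_id))
    stop("duplicate ref_id in taxonomy table", call. = FALSE)
  tax[need]
}

#' Write a taxonomy table (TSV)
#' @param tax data frame with ref_id, species, group, lineage
#' @param path output path
#' @export
write_taxonomy <- function(tax, path) {
  write.table(tax[c("ref_id", "species", "group", "lineage")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
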