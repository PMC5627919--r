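#' Greedy abundance-ordered clustering of unique sequences
#'
#' The most abundant unique seeds the first cluster; each subsequent unique
#' joins the first existing centroid whose pairwise identity is at least
#' `identity_threshold`, otherwise it seeds a new cluster. Centroids are the
#' seeding uniques themselves (most abundant exact reads), not consensus
#' sequences.
#'
#' @param uniques a `derep` object sorted by abundance descending
#' @param identity_threshold percent identity to join a cluster; default 97
#' @return list of clusters sorted by total abundance descending; each is a
#'   list with `centroid` (sequence), `centroid_index`, `members` (indices
#'   into `uniques`), `total_abundance`
#' @export
greedy_cluster <- function(uniques, identity_threshold = 97) {
  n <- length(uniques$bases)
  if (n == 0L) return(list())
  cent_idx <- integer(0)
  members <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_along(cent_idx)) {
      if (.identity_at_least(uniques$bases[cent_idx[k]], uniques$bases[i],
                             identity_threshold)) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_idx <- c(cent_idx, i)
      members[[length(cent_idx)]] <- i
    }
  }
  clusters <- lapply(seq_along(cent_idx), function(k) {
    list(centroid = uniques$bases[cent_idx[k]],
         centroid_index = cent_idx[k],
         members = members[[k]],
         total_abundance = sum(uniques$abundance[members[[k]]]))
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "total_abundance"))
  clusters[ord]
}

#' Translate a nucleotide sequence in a given frame
#'
#' The trailing partial codon is dropped; stop codons render as `*`; any
#' codon containing an ambiguous base renders as `X`. The default genetic
#' code is table 5 (invertebrate mitochondrial: AGA/AGG = Ser, TGA = Trp,
#' ATA = Met), the code of the zooplankton COI marker.
#'
#' @param bases nucleotide string (no gaps)
#' @param frame 0, 1 or 2
#' @param code NCBI genetic code id as a string; default `"5"`
#' @return amino-acid string
#' @export
translate_dna <- function(bases, frame = 0L, code = "5") {
  stopifnot(frame %in% 0:2)
  bases <- normalize_bases(bases)
  if (grepl("-", bases, fixed = TRUE))
    stop("cannot translate gapped sequence", call. = FALSE)
  sub <- substr(bases, frame + 1L, nchar(bases))
  len <- (nchar(sub) %/% 3L) * 3L
  if (len < 3L)
    stop("fewer than one codon after frame offset", call. = FALSE)
  tab <- .genetic_code(code)
  codons <- substring(sub, seq(1L, len, 3L), seq(3L, len, 3L))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"   # any codon containing an ambiguous base
  paste(aa, collapse = "")
}

# memoized NCBI genetic code tables (codon -> amino acid, '*' for stops)
.gc_cache <- new.env(parent = emptyenv())
.genetic_code <- function(code) {
  if (is.null(.gc_cache[[code]]))
    .gc_cache[[code]] <- Biostrings::getGeneticCode(code)
  .gc_cache[[code]]
}

#' Read a labeled amino-acid screening panel
#'
#' FASTA of amino-acid sequences whose description field starts with the
#' label `target_COI` or `bacterial_COI`, e.g.
#' `>cladoceran_sp1 target_COI`.
#'
#' @param path FASTA path
#' @return data frame with columns id, label, aa
#' @export
read_panel <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  full <- names(set)
  id <- sub("[ \t].*$", "", full)
  label <- ifelse(grepl("[ \t]", full),
                  sub("^[^ \t]+[ \t]+([^ \t]+).*$", "\\1", full), "")
  panel(id, label, as.character(set))
}

#' Construct a screening panel
#' @param id entry ids
#' @param label `"target_COI"` or `"bacterial_COI"` per entry
#' @param aa amino-acid strings
#' @return data frame of class `aa_panel`
#' @export
panel <- function(id, label, aa) {
  bad <- !label %in% c("target_COI", "bacterial_COI")
  if (any(bad))
    stop("panel labels must be target_COI or bacterial_COI (offender: ",
         id[bad][1], ")", call. = FALSE)
  out <- data.frame(id = as.character(id), label = as.character(label),
                    aa = toupper(as.character(aa)), stringsAsFactors = FALSE)
  class(out) <- c("aa_panel", "data.frame")
  out
}

#' Write a screening panel as amino-acid FASTA
#' @param pan an `aa_panel`
#' @param path output path
#' @export
write_panel <- function(pan, path) {
  set <- Biostrings::AAStringSet(pan$aa)
  names(set) <- paste(pan$id, pan$label)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Coding plausibility screen of a cluster centroid
#'
#' Translates the centroid in the three forward frames (reads are already
#' primer-oriented), marks frames without internal stop codons, and scores
#' each stop-free frame's translation against the screening panel by global
#' amino-acid alignment. A terminal stop (last complete codon) does not
#' disqualify a frame. The mitochondrial COI fragment of a real specimen
#' has exactly one stop-free frame; NUMT pseudogenes and frame-shifted
#' artifacts typically have none.
#'
#' @param bases centroid sequence (>= `min_length` bases)
#' @param pan an `aa_panel`
#' @param code genetic code id; default `"5"`
#' @param min_length minimum centroid length; default 30
#' @return list: `stop_free` (any stop-free frame), `best_frame` (0-2 or
#'   NA; the stop-free frame with highest panel identity, ties to the
#'   lowest frame), `aa` (best-frame translation), `aa_identity`,
#'   `best_hit` (panel row index), `frames` (per-frame diagnostics), or
#'   `ok = FALSE` with a `reason` for centroids shorter than `min_length`
#' @export
coding_screen <- function(bases, pan, code = "5", min_length = 30L) {
  if (nchar(bases) < min_length)
    return(list(ok = FALSE, reason = "too short", stop_free = FALSE,
                best_frame = NA_integer_, aa = NA_character_,
                aa_identity = 0, best_hit = NA_integer_))
  frames <- lapply(0:2, function(f) {
    aa <- translate_dna(bases, f, code)
    internal <- substr(aa, 1L, nchar(aa) - 1L)
    sf <- !grepl("*", internal, fixed = TRUE)
    ident <- 0; hit <- NA_integer_
    if (sf && nrow(pan) > 0L) {
      st <- pairwise_identity_many(pan$aa, aa)
      hit <- which.max(st[, "identity"])
      ident <- unname(st[hit, "identity"])
    }
    list(frame = f, aa = aa, stop_free = sf, aa_identity = ident, best_hit = hit)
  })
  sf <- vapply(frames, `[[`, logical(1), "stop_free")
  if (!any(sf))
    return(list(ok = TRUE, stop_free = FALSE, best_frame = NA_integer_,
                aa = NA_character_, aa_identity = 0, best_hit = NA_integer_,
                frames = frames))
  ident <- vapply(frames, `[[`, numeric(1), "aa_identity")
  ident[!sf] <- -Inf
  best <- which.max(ident)  # ties resolve to the lowest frame index
  list(ok = TRUE, stop_free = TRUE, best_frame = best - 1L,
       aa = frames[[best]]$aa, aa_identity = frames[[best]]$aa_identity,
       best_hit = frames[[best]]$best_hit, frames = frames)
}

#' Classify a screened cluster by its best panel hit
#'
#' The best-frame translation is globally aligned to every panel entry; the
#' cluster takes the label of the best hit if the amino-acid identity
#' reaches `min_aa_identity`, else `"unknown"`. Clusters with no stop-free
#' frame are `"unknown"` with identity 0.
#'
#' @param screen result of [coding_screen()]
#' @param pan the `aa_panel` used for screening
#' @param min_aa_identity percent; default 60
#' @return list: `taxon_label`, `aa_identity`, `best_hit_id`
#' @export
classify_cluster <- function(screen, pan, min_aa_identity = 60) {
  if (!isTRUE(screen$stop_free) || is.na(screen$best_hit))
    return(list(taxon_label = "unknown", aa_identity = 0,
                best_hit_id = NA_character_))
  if (screen$aa_identity >= min_aa_identity)
    list(taxon_label = pan$label[screen$best_hit],
         aa_identity = screen$aa_identity,
         best_hit_id = pan$id[screen$best_hit])
  else
    list(taxon_label = "unknown", aa_identity = screen$aa_identity,
         best_hit_id = pan$id[screen$best_hit])
}

#' Recover the barcode of one specimen from its pre-treated reads
#'
#' Pipeline: dereplicate, remove de-novo chimeras, greedy-cluster, screen
#' and classify every cluster, then pick the most abundant cluster that is
#' both stop-free and labeled `target_COI`. The barcode is that cluster's
#' centroid; `support` is its read fraction among the specimen's retained
#' reads (the reads entering recovery, before chimera removal). If a non-target cluster outranks the chosen one the record is
#' flagged `contaminant-majority`; with no qualifying cluster a failure
#' record with per-cluster diagnostics is returned.
#'
#' With `representative = "consensus"` the barcode is instead the
#' abundance-weighted majority consensus of the chosen cluster's members
#' (in centroid coordinates); a consensus that fails the coding screen
#' falls back to the centroid with a flag.
#'
#' @param reads `seq_records` of one specimen, already quality/primer/length
#'   filtered, or a `derep` object
#' @param pan an `aa_panel`
#' @param specimen_id label for the output record
#' @param identity_threshold within-specimen clustering identity; default 97
#' @param min_aa_identity panel classification threshold; default 60
#' @param code genetic code id; default `"5"`
#' @param representative `"centroid"` (default: the cluster's most abundant
#'   exact read) or `"consensus"`
#' @return list of class `barcode_recovery`: `success`, `specimen_id`,
#'   `bases`, `support`, `flags`, `reason`, `clusters` (diagnostics frame)
#' @export
recover_barcode <- function(reads, pan, specimen_id = "specimen",
                            identity_threshold = 97, min_aa_identity = 60,
                            code = "5",
                            representative = c("centroid", "consensus")) {
  representative <- match.arg(representative)
  uniques <- if (inherits(reads, "derep")) reads else dereplicate(reads)
  fail <- function(reason, clusters = NULL) {
    structure(list(success = FALSE, specimen_id = specimen_id,
                   bases = NA_character_, support = NA_real_,
                   flags = character(0), reason = reason,
                   clusters = clusters),
              class = "barcode_recovery")
  }
  if (length(uniques$bases) == 0L) return(fail("no reads"))
  retained <- sum(uniques$abundance)  # support denominator: pre-chimera-removal
  chim <- detect_chimeras(uniques)
  uniques <- derep_subset(uniques, which(!chim$flagged))
  if (length(uniques$bases) == 0L) return(fail("no reads"))
  clusters <- greedy_cluster(uniques, identity_threshold)

  diag <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    scr <- coding_screen(cl$centroid, pan, code)
    cls <- classify_cluster(scr, pan, min_aa_identity)
    data.frame(cluster = k, total_abundance = cl$total_abundance,
               stop_free = isTRUE(scr$stop_free),
               best_frame = if (is.na(scr$best_frame)) NA_integer_ else scr$best_frame,
               taxon_label = cls$taxon_label, aa_identity = cls$aa_identity,
               best_hit_id = if (is.na(cls$best_hit_id)) NA_character_ else cls$best_hit_id,
               stringsAsFactors = FALSE)
  }))

  ok <- which(diag$stop_free & diag$taxon_label == "target_COI")
  if (!length(ok)) return(fail("no qualifying cluster", diag))
  chosen <- ok[1]  # clusters are abundance-sorted
  flags <- character(0)
  if (chosen > 1L && any(diag$taxon_label[seq_len(chosen - 1L)] != "target_COI"))
    flags <- "contaminant-majority"
  bases <- clusters[[chosen]]$centroid
  if (representative == "consensus") {
    cons <- .cluster_consensus(uniques, clusters[[chosen]])
    scr <- coding_screen(cons, pan, code)
    if (isTRUE(scr$stop_free)) bases <- cons
    else flags <- c(flags, "consensus-failed-screen")
  }
  structure(list(success = TRUE, specimen_id = specimen_id,
                 bases = bases,
                 support = clusters[[chosen]]$total_abundance / retained,
                 flags = flags, reason = "",
                 clusters = diag),
            class = "barcode_recovery")
}

# abundance-weighted majority consensus of a cluster, in centroid
# coordinates; members of other lengths are globally aligned to the
# centroid first. Column ties resolve in A < C < G < T < gap order;
# gap-majority columns are removed.
.cluster_consensus <- function(uniques, cluster) {
  centroid <- cluster$centroid
  L <- nchar(centroid)
  alphabet <- c("A", "C", "G", "T", "-")
  counts <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (m in cluster$members) {
    s <- uniques$bases[m]
    w <- uniques$abundance[m]
    if (nchar(s) == L) {
      v <- strsplit(s, "", fixed = TRUE)[[1]]
    } else {
      al <- pairwise_identity(centroid, s, keep_alignment = TRUE)
      cv <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
      sv <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      v <- sv[cv != "-"]
    }
    ok <- v %in% alphabet
    if (any(ok))
      counts[cbind(match(v[ok], alphabet), which(ok))] <-
        counts[cbind(match(v[ok], alphabet), which(ok))] + w
  }
  cons <- alphabet[apply(counts, 2L, which.max)]
  paste(cons[cons != "-"], collapse = "")
}

#' @export
print.barcode_recovery <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<barcode_recovery> %s: %d bp, support %.2f%s\n",
                x$specimen_id, nchar(x$bases), x$support,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
  } else {
    cat(sprintf("<barcode_recovery> %s: FAILED (%s)\n", x$specimen_id, x$reason))
  }
  invisible(x)
}

#' Assemble recovered barcodes into a reference database
#'
#' @param barcodes data frame with columns specimen_id, species, bases (one
#'   successful recovery per row); the `support`/`flags` columns are carried
#'   through when present
#' @param taxonomy data frame with ref_id, species, group, lineage; every
#'   specimen_id must resolve to a ref_id
#' @param name database name (e.g. `"indigenous"`)
#' @return object of class `reference_db`: `name`, `seq` (named character
#'   vector ref_id -> bases), `taxonomy`
#' @export
build_database <- function(barcodes, taxonomy, name = "indigenous") {
  if (nrow(barcodes) == 0L) {
    warning("building an empty reference database")
    return(reference_db(character(0), character(0),
                        taxonomy[0, , drop = FALSE], name))
  }
  if (anyDuplicated(barcodes$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(barcodes$specimen_id[duplicated(barcodes$specimen_id)]),
               collapse = ", "), call. = FALSE)
  miss <- setdiff(barcodes$specimen_id, taxonomy$ref_id)
  if (length(miss))
    stop("no taxonomy entry for specimen(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tax <- taxonomy[match(barcodes$specimen_id, taxonomy$ref_id), , drop = FALSE]
  reference_db(barcodes$specimen_id, barcodes$bases, tax, name)
}

#' Construct a reference barcode database
#' @param ref_id unique reference ids
#' @param bases barcode sequences
#' @param taxonomy data frame with ref_id, species, group, lineage rows
#'   matching `ref_id`
#' @param name database name
#' @return a `reference_db` object
#' @export
reference_db <- function(ref_id, bases, taxonomy, name = "db") {
  ref_id <- as.character(ref_id)
  if (anyDuplicated(ref_id))
    stop("duplicate ref_id in reference database", call. = FALSE)
  taxonomy <- taxonomy[match(ref_id, taxonomy$ref_id), , drop = FALSE]
  if (length(ref_id) && anyNA(taxonomy$ref_id))
    stop("taxonomy missing for some references", call. = FALSE)
  if (length(ref_id) && any(!nzchar(taxonomy$species) & !nzchar(taxonomy$lineage)))
    stop("every reference needs a species or higher-rank label", call. = FALSE)
  rownames(taxonomy) <- NULL
  structure(list(name = name,
                 seq = setNames(normalize_bases(as.character(bases)), ref_id),
                 taxonomy = taxonomy),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> '%s': %d sequences, %d species\n", x$name,
              length(x$seq), length(unique(x$taxonomy$species[nzchar(x$taxonomy$species)]))))
  invisible(x)
}

#' Write a reference database (FASTA + taxonomy TSV)
#' @param db a `reference_db`
#' @param fasta_path,taxonomy_path output paths
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path) {
  write_fasta(db$seq, fasta_path)
  write_taxonomy(db$taxonomy, taxonomy_path)
  invisible(db)
}

#' Read a reference database from FASTA + taxonomy TSV
#' @param fasta_path,taxonomy_path input paths
#' @param name database name
#' @return a `reference_db`
#' @export
read_reference_db <- function(fasta_path, taxonomy_path, name = "db") {
  seqs <- read_fasta(fasta_path)
  tax <- read_taxonomy(taxonomy_path)
  reference_db(seqs$id, seqs$bases, tax, name)
}
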