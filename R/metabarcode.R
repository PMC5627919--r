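#' Greedy centroid OTU clustering of pooled community uniques
#'
#' Abundance-ordered greedy clustering in the style of the UPARSE pipeline:
#' a unique sequence joins the first OTU whose representative is at least
#' `radius` percent identical, otherwise — if its abundance reaches
#' `min_abundance` and it is not chimera-flagged — it seeds a new OTU.
#' Low-abundance uniques never seed but are still mapped onto existing
#' OTUs; chimera-flagged uniques are dropped entirely.
#'
#' @param uniques pooled `derep` object (abundance-sorted), ideally with a
#'   per-sample count matrix
#' @param radius percent identity radius; default 97
#' @param min_abundance minimum abundance to seed an OTU; default 2
#' @param chimera_flags optional logical vector (one per unique)
#' @return list of class `otu_set`: `otus` (data frame otu_id,
#'   representative, total_reads), `sample_counts` (OTU x sample matrix, if
#'   sample counts were present), `members` (list of unique indices)
#' @export
cluster_otus <- function(uniques, radius = 97, min_abundance = 2L,
                         chimera_flags = NULL) {
  n <- length(uniques$bases)
  if (is.null(chimera_flags)) chimera_flags <- rep(FALSE, n)
  stopifnot(length(chimera_flags) == n)
  reps <- character(0)
  members <- list()
  for (i in seq_len(n)) {
    if (chimera_flags[i]) next
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (.identity_at_least(reps[k], uniques$bases[i], radius)) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed && uniques$abundance[i] >= min_abundance) {
      reps <- c(reps, uniques$bases[i])
      members[[length(reps)]] <- i
    }
  }
  if (!length(reps))
    return(structure(list(
      otus = data.frame(otu_id = character(0), representative = character(0),
                        total_reads = integer(0), stringsAsFactors = FALSE),
      sample_counts = NULL, members = list()), class = "otu_set"))
  total <- vapply(members, function(mm) sum(uniques$abundance[mm]), numeric(1))
  ord <- order(-total)
  otu_id <- sprintf("OTU_%d", seq_along(ord))
  otus <- data.frame(otu_id = otu_id, representative = reps[ord],
                     total_reads = as.integer(total[ord]),
                     stringsAsFactors = FALSE)
  sc <- NULL
  if (!is.null(uniques$samples)) {
    sc <- t(vapply(members[ord], function(mm)
      colSums(uniques$samples[mm, , drop = FALSE]),
      numeric(ncol(uniques$samples))))
    rownames(sc) <- otu_id
  }
  structure(list(otus = otus, sample_counts = sc, members = members[ord]),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("<otu_set> %d OTUs, %d reads\n", nrow(x$otus),
              sum(x$otus$total_reads)))
  invisible(x)
}

#' Assign an OTU representative to a taxon against a reference database
#'
#' The representative is globally aligned to every reference; the best hit
#' is chosen by identity (ties: longer alignment, then lexicographic
#' ref_id). The OTU is assigned at species level iff identity is strictly
#' greater than `min_identity` percent AND the alignment length (columns
#' excluding terminal gaps) is strictly greater than
#' `min_alignment_length`; otherwise the best hit is retained but the OTU
#' is reported unassigned at species rank.
#'
#' @param representative the OTU representative sequence
#' @param db a `reference_db`
#' @param min_identity percent, strict; default 95
#' @param min_alignment_length bases, strict; default 100
#' @return one-row data frame: database_name, best_ref_id, species,
#'   identity, alignment_length, assigned_at_species
#' @export
assign_taxonomy <- function(representative, db, min_identity = 95,
                            min_alignment_length = 100L) {
  if (!length(db$seq)) stop("reference database is empty", call. = FALSE)
  st <- pairwise_identity_many(unname(db$seq), representative)
  ids <- names(db$seq)
  ord <- order(-st[, "identity"], -st[, "columns"], ids, method = "radix")
  best <- ord[1]
  species <- db$taxonomy$species[match(ids[best], db$taxonomy$ref_id)]
  data.frame(database_name = db$name,
             best_ref_id = ids[best],
             species = species,
             identity = st[best, "identity"],
             alignment_length = as.integer(st[best, "columns"]),
             assigned_at_species = st[best, "identity"] > min_identity &
               st[best, "columns"] > min_alignment_length,
             stringsAsFactors = FALSE)
}

#' Assign every OTU in a set against a reference database
#' @param otu_set an `otu_set`
#' @param db a `reference_db`
#' @param min_identity,min_alignment_length see [assign_taxonomy()]
#' @return data frame with one row per OTU (otu_id first column)
#' @export
assign_otus <- function(otu_set, db, min_identity = 95,
                        min_alignment_length = 100L) {
  rows <- lapply(seq_len(nrow(otu_set$otus)), function(i)
    cbind(otu_id = otu_set$otus$otu_id[i],
          assign_taxonomy(otu_set$otus$representative[i], db,
                          min_identity, min_alignment_length),
          stringsAsFactors = FALSE))
  if (!length(rows))
    return(data.frame(otu_id = character(0), database_name = character(0),
                      best_ref_id = character(0), species = character(0),
                      identity = numeric(0), alignment_length = integer(0),
                      assigned_at_species = logical(0)))
  do.call(rbind, rows)
}

#' Compare species-level assignment between two reference databases
#'
#' Classifies each OTU as species-assigned by `both`, `local-only`,
#' `ncbi-only` (names follow the two inputs) or `neither`, and for the
#' `both` class records whether the two databases agree on the species.
#'
#' @param assignments_local,assignments_ncbi [assign_otus()] frames over
#'   the same OTU id set
#' @return list: `per_otu` (otu_id, class, species_local, species_ncbi,
#'   species_agree), `summary` (class counts)
#' @export
compare_databases <- function(assignments_local, assignments_ncbi) {
  a <- assignments_local
  b <- assignments_ncbi
  if (!setequal(a$otu_id, b$otu_id) || nrow(a) != nrow(b))
    stop("the two assignment sets cover different OTU ids", call. = FALSE)
  b <- b[match(a$otu_id, b$otu_id), , drop = FALSE]
  cls <- ifelse(a$assigned_at_species & b$assigned_at_species, "both",
         ifelse(a$assigned_at_species, "local-only",
         ifelse(b$assigned_at_species, "ncbi-only", "neither")))
  agree <- ifelse(cls == "both", a$species == b$species, NA)
  per_otu <- data.frame(otu_id = a$otu_id, class = cls,
                        species_local = ifelse(a$assigned_at_species,
                                               a$species, NA_character_),
                        species_ncbi = ifelse(b$assigned_at_species,
                                              b$species, NA_character_),
                        species_agree = agree, stringsAsFactors = FALSE)
  summary <- as.data.frame(table(factor(cls, levels = c("both", "local-only",
                                                        "ncbi-only", "neither"))),
                           stringsAsFactors = FALSE)
  names(summary) <- c("class", "n_otus")
  list(per_otu = per_otu, summary = summary)
}

#' Write an OTU table as TSV
#' @param otu_set an `otu_set`
#' @param path output path
#' @export
write_otu_table <- function(otu_set, path) {
  tab <- otu_set$otus
  if (!is.null(otu_set$sample_counts))
    tab <- cbind(tab, as.data.frame(otu_set$sample_counts))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
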