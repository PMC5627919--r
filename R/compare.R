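#' Abundance-frequency category of a species
#'
#' Categories follow the survey convention: abundant when detected in more
#' than half the samples, moderate when in more than a third (up to a
#' half), rare otherwise. A frequency of exactly 1/3 falls in `rare` (the
#' bounds "> 1/3" and "< 1/3" leave the point ambiguous; it is resolved
#' downward).
#'
#' @param freq detection frequency (fraction of samples), in \[0, 1\];
#'   vectorized
#' @return character vector in `{"abundant", "moderate", "rare"}`
#' @export
frequency_categories <- function(freq) {
  if (any(is.na(freq)) || any(freq < 0 | freq > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  ifelse(freq > 1 / 2, "abundant", ifelse(freq > 1 / 3, "moderate", "rare"))
}

#' Build a two-method species x sample detection table
#'
#' @param morphology,metabarcoding data frames with columns `species` and
#'   `sample` (one row per detection), or logical species x sample matrices
#' @param synonyms optional data frame (`from`, `to`) applied to species
#'   names of both layers after whitespace/case normalization
#' @return list of class `detection_table`: `morphology` and
#'   `metabarcoding` logical matrices over the union of species and of
#'   samples, plus `frequency` (per species and method)
#' @export
detection_table <- function(morphology, metabarcoding, synonyms = NULL) {
  norm <- function(x) {
    x <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
    if (!is.null(synonyms)) {
      hit <- match(x, tolower(trimws(synonyms$from)))
      x[!is.na(hit)] <- tolower(trimws(synonyms$to))[hit[!is.na(hit)]]
    }
    x
  }
  as_pairs <- function(x) {
    if (is.matrix(x)) {
      idx <- which(x, arr.ind = TRUE)
      data.frame(species = norm(rownames(x)[idx[, 1]]),
                 sample = colnames(x)[idx[, 2]], stringsAsFactors = FALSE)
    } else {
      data.frame(species = norm(x$species), sample = as.character(x$sample),
                 stringsAsFactors = FALSE)
    }
  }
  mo <- as_pairs(morphology)
  mb <- as_pairs(metabarcoding)
  species <- sort(unique(c(mo$species, mb$species)))
  samples <- sort(unique(c(mo$sample, mb$sample,
                           if (is.matrix(morphology)) colnames(morphology),
                           if (is.matrix(metabarcoding)) colnames(metabarcoding))))
  layer <- function(p) {
    m <- matrix(FALSE, length(species), length(samples),
                dimnames = list(species, samples))
    m[cbind(p$species, p$sample)] <- TRUE
    m
  }
  L1 <- layer(mo)
  L2 <- layer(mb)
  freq <- data.frame(species = species,
                     morphology = rowMeans(L1),
                     metabarcoding = rowMeans(L2),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(morphology = L1, metabarcoding = L2, frequency = freq),
            class = "detection_table")
}

#' Per-sample species-count concordance regression
#'
#' Ordinary least squares of the metabarcoding species count on the
#' morphology species count across samples; R-squared is the squared
#' Pearson correlation and p the two-sided t-test on the slope.
#'
#' @param x per-sample species counts by morphology
#' @param y per-sample species counts by metabarcoding
#' @return list: slope, intercept, r_squared, p_value, n
#' @export
concordance_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in the morphology counts",
                               call. = FALSE)
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, p_value = s$coefficients[2, 4],
       n = length(x))
}

#' Cell-wise agreement between the two detection layers
#'
#' A species x sample cell is consistent iff both methods agree on
#' presence/absence; the consistency rate is the fraction of consistent
#' cells.
#'
#' @param table a `detection_table`
#' @return list: `consistent` (logical matrix), `rate`
#' @export
detection_equivalency <- function(table) {
  cons <- table$morphology == table$metabarcoding
  list(consistent = cons, rate = mean(cons))
}

#' Composition summary of a reference database by taxonomic group
#'
#' @param db a `reference_db`
#' @return data frame: group (Cladocera, Copepoda, Rotifera, other),
#'   n_sequences, n_species; totals over rows equal the database size
#' @export
db_composition_summary <- function(db) {
  groups <- c("Cladocera", "Copepoda", "Rotifera", "other")
  tax <- db$taxonomy
  g <- ifelse(tax$group %in% groups[1:3], tax$group, "other")
  data.frame(group = groups,
             n_sequences = vapply(groups, function(gr) sum(g == gr), integer(1)),
             n_species = vapply(groups, function(gr)
               length(unique(tax$species[g == gr & nzchar(tax$species)])),
               integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
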