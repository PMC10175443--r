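# Partition pairwise dissimilarities into the five variation sources the
# nested design isolates: two technical (library prep, DNA extraction) and
# three biological (daily, weekly, between-subject). Each category changes
# exactly one design variable at a time; pairs differing in several
# variables at once (other than subject) are left unclassified.

.CATEGORIES <- c("LIBPREP", "EXTRACTION", "DAILY", "WEEKLY", "SUBJECT")

#' Variation-source categories
#' @return character vector of the five categories, technical first.
#' @export
variation_categories <- function() .CATEGORIES

classify_core <- function(subj_a, subj_b, day_a, day_b, week_a, week_b,
                          ext_a, ext_b, lib_a, lib_b) {
  if (subj_a != subj_b) return("SUBJECT")
  gap <- abs(day_a - day_b)
  if (day_a == day_b) {
    if (ext_a == ext_b && lib_a != lib_b) return("LIBPREP")
    if (lib_a == lib_b && ext_a != ext_b) return("EXTRACTION")
    return(NA_character_)
  }
  if (gap == 1 && week_a == week_b) return("DAILY")
  if (gap == 7) return("WEEKLY")
  NA_character_
}

#' Classify a sample pair into a variation-source category
#'
#' LIBPREP: same subject, day and extraction, different library prep.
#' EXTRACTION: same subject, day and library-prep index, different
#' extraction. DAILY: same subject, consecutive days within a week (any
#' replicates). WEEKLY: same subject, days exactly 7 apart. SUBJECT:
#' different subjects. Anything else (e.g. both replicate indices differing
#' on the same day, or day gaps of 6 or 8) is unclassified (`NA`).
#'
#' @param meta_a,meta_b single-row data.frames (or lists) with subject, day,
#'   week, extraction_rep, libprep_rep, modality.
#' @return one of [variation_categories()] or `NA_character_`.
#' @export
classify_pair <- function(meta_a, meta_b) {
  if (meta_a$modality != meta_b$modality)
    abort("cannot classify a pair of mixed modalities")
  classify_core(meta_a$subject, meta_b$subject, meta_a$day, meta_b$day,
                meta_a$week, meta_b$week, meta_a$extraction_rep,
                meta_b$extraction_rep, meta_a$libprep_rep, meta_b$libprep_rep)
}

#' Partition a dissimilarity matrix by variation source
#'
#' Emits one record per unordered sample pair that falls into a category.
#' On the default 5 subjects x 4 days x 2 x 2 design this yields 40 LIBPREP,
#' 40 EXTRACTION, 160 DAILY, 160 WEEKLY and 2560 SUBJECT pairs out of
#' C(80,2) = 3160 (200 unclassified).
#'
#' @param D symmetric dissimilarity matrix over one modality's samples.
#' @param metadata design data.frame covering all samples of `D`.
#' @return data.frame(sample_a, sample_b, modality, category, dissimilarity);
#'   the number of unclassified pairs is in `attr(, "n_unclassified")`.
#' @export
partition_dissimilarities <- function(D, metadata) {
  D <- as.matrix(D)
  ids <- rownames(D)
  m <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(m$sample_id))
    abort("samples missing from metadata: %s",
          paste(ids[is.na(m$sample_id)], collapse = ", "))
  if (length(unique(m$modality)) > 1L)
    abort("distance matrix spans multiple modalities")
  n <- length(ids)
  if (n < 2L) {
    out <- data.frame(sample_a = character(0), sample_b = character(0),
                      modality = character(0), category = character(0),
                      dissimilarity = numeric(0))
    attr(out, "n_unclassified") <- 0L
    return(out)
  }
  pairs <- utils::combn(n, 2L)
  i <- pairs[1, ]; j <- pairs[2, ]
  cat_v <- vapply(seq_along(i), function(k) {
    classify_core(m$subject[i[k]], m$subject[j[k]], m$day[i[k]], m$day[j[k]],
                  m$week[i[k]], m$week[j[k]],
                  m$extraction_rep[i[k]], m$extraction_rep[j[k]],
                  m$libprep_rep[i[k]], m$libprep_rep[j[k]])
  }, character(1))
  keep <- !is.na(cat_v)
  out <- data.frame(
    sample_a = ids[i[keep]], sample_b = ids[j[keep]],
    modality = m$modality[1], category = cat_v[keep],
    dissimilarity = D[cbind(i[keep], j[keep])],
    stringsAsFactors = FALSE
  )
  attr(out, "n_unclassified") <- sum(!keep)
  out
}

#' Genus-level concordance between two modalities
#'
#' Collapses both relative-abundance tables to genus (features lacking a
#' genus are excluded), matches samples one-to-one on (subject, day,
#' extraction_rep, libprep_rep), zero-fills genera absent from one table,
#' and correlates the pooled sample x genus cells (Pearson and Spearman).
#'
#' @param table_amplicon,table_shotgun relative-abundance matrices whose
#'   rownames are lineage strings.
#' @param metadata design covering both modalities' samples.
#' @param per_sample if TRUE, additionally return the mean of per-sample
#'   correlations instead of only the pooled ones.
#' @return list(pearson_r, spearman_rho, n_cells) plus, with
#'   `per_sample = TRUE`, `pearson_r_per_sample` and
#'   `spearman_rho_per_sample`.
#' @export
genus_concordance <- function(table_amplicon, table_shotgun, metadata,
                              per_sample = FALSE) {
  collapse_genus <- function(tab) {
    g <- lineage_rank_value(rownames(tab), "genus")
    keep <- !is.na(g)
    rowsum(tab[keep, , drop = FALSE], group = g[keep], reorder = TRUE)
  }
  ga <- collapse_genus(table_amplicon)
  gs <- collapse_genus(table_shotgun)

  key <- function(ids) {
    m <- metadata[match(ids, metadata$sample_id), ]
    if (anyNA(m$sample_id)) abort("concordance: samples missing from metadata")
    paste(m$subject, m$day, m$extraction_rep, m$libprep_rep)
  }
  ka <- key(colnames(ga)); ks <- key(colnames(gs))
  common <- intersect(ka, ks)
  if (length(common) == 0L) abort("no matched samples between modalities")
  if (length(common) < length(ka) || length(common) < length(ks))
    warn("dropping unmatched samples: %d amplicon, %d shotgun",
         sum(!(ka %in% common)), sum(!(ks %in% common)))
  ga <- ga[, match(common, ka), drop = FALSE]
  gs <- gs[, match(common, ks), drop = FALSE]

  genera <- sort(union(rownames(ga), rownames(gs)))
  fill <- function(tab) {
    out <- matrix(0, length(genera), ncol(tab),
                  dimnames = list(genera, colnames(tab)))
    out[rownames(tab), ] <- tab
    out
  }
  A <- fill(ga); S <- fill(gs)
  res <- list(
    pearson_r = stats::cor(as.vector(A), as.vector(S), method = "pearson"),
    spearman_rho = stats::cor(as.vector(A), as.vector(S), method = "spearman"),
    n_cells = length(A)
  )
  if (per_sample) {
    pr <- vapply(seq_len(ncol(A)), function(s)
      stats::cor(A[, s], S[, s], method = "pearson"), numeric(1))
    sr <- vapply(seq_len(ncol(A)), function(s)
      stats::cor(A[, s], S[, s], method = "spearman"), numeric(1))
    res$pearson_r_per_sample <- mean(pr)
    res$spearman_rho_per_sample <- mean(sr)
  }
  res
}

#' Abundance-weighted taxonomic resolution summary
#'
#' For each rank, the fraction of total abundance carried by features
#' assigned at that rank or deeper. Monotone nonincreasing with depth;
#' equals 1 at kingdom for fully assigned tables.
#'
#' @param taxa_table feature x sample matrix with lineage-string rownames.
#' @return named numeric vector over [lineage_ranks()].
#' @export
resolution_summary <- function(taxa_table) {
  if (nrow(taxa_table) == 0L) abort("empty taxa table")
  w <- rowSums(taxa_table)
  total <- sum(w)
  if (total == 0) abort("taxa table has zero total abundance")
  depth <- lineage_depth(rownames(taxa_table))
  stats::setNames(vapply(seq_along(.RANKS), function(d)
    sum(w[depth >= d]) / total, numeric(1)), .RANKS)
}

#' Most abundant features of a relative-abundance table
#'
#' @param table feature x sample relative-abundance matrix.
#' @param n number of features to return (default 20).
#' @return data.frame(feature, mean_abundance) sorted by decreasing mean
#'   abundance across samples, ties broken lexicographically by feature id.
#' @export
top_taxa <- function(table, n = 20L) {
  m <- rowMeans(table)
  ord <- order(-m, rownames(table))
  k <- min(n, nrow(table))
  data.frame(feature = rownames(table)[ord][seq_len(k)],
             mean_abundance = unname(m[ord])[seq_len(k)],
             stringsAsFactors = FALSE)
}
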