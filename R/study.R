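#' Simulate one replicate study and partition its variation
#'
#' Convenience for replicate-level analyses (parameter recovery, power):
#' simulates the design, latent and measured compositions, draws count
#' tables at the configured depths, converts to relative abundance,
#' computes Bray-Curtis dissimilarities per modality and classifies every
#' sample pair into its variation-source category. This operates on the
#' measured taxon count tables directly; the read-level profiling path
#' changes feature naming and resolution but not the replicate variance
#' structure this function measures.
#'
#' @param config a [simulation_config()].
#' @param seed optional override of `config$seed` for this replicate.
#' @return data.frame of variation records for both modalities
#'   (columns sample_a, sample_b, modality, category, dissimilarity).
#' @export
simulate_variation_records <- function(config, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  design <- simulate_design(config)
  profiles <- simulate_profiles(config, design)
  counts <- simulate_count_tables(profiles, design, config)
  recs <- lapply(c("AMPLICON", "SHOTGUN"), function(mod) {
    ids <- design$sample_id[design$modality == mod]
    rel <- to_relative_abundance(counts[, ids, drop = FALSE])
    partition_dissimilarities(bray_curtis_matrix(rel), design)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Median dissimilarity per variation category
#'
#' @param records variation records (one modality or pooled).
#' @return named numeric vector over the categories present.
#' @export
category_medians <- function(records) {
  vapply(split(records$dissimilarity, records$category), stats::median,
         numeric(1))
}
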