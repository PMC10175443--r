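#' Enumerate the nested sampling design
#'
#' Expands the configured design into one sample record per combination of
#' subject, day, extraction replicate, library-prep replicate and modality.
#' Week is derived from day (days 1-7 are week 1, days 8-14 week 2, ...).
#' The enumeration is purely combinatorial and deterministic.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns sample_id, subject, day, week,
#'   extraction_rep, libprep_rep, modality; one row per sample, both
#'   modalities included.
#' @export
simulate_design <- function(config) {
  validate_config(config)
  grid <- expand.grid(
    libprep_rep = seq_len(config$n_libpreps),
    extraction_rep = seq_len(config$n_extractions),
    day = config$days,
    subject = sprintf("S%d", seq_len(config$n_subjects)),
    modality = c("AMPLICON", "SHOTGUN"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$week <- (grid$day - 1L) %/% 7L + 1L
  grid$sample_id <- sprintf("%s_%s_d%d_e%d_l%d", grid$modality, grid$subject,
                            grid$day, grid$extraction_rep, grid$libprep_rep)
  meta <- grid[, c("sample_id", "subject", "day", "week",
                   "extraction_rep", "libprep_rep", "modality")]
  rownames(meta) <- NULL
  stopifnot(!anyDuplicated(meta$sample_id))
  meta
}
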