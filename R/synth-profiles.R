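#' Simulate latent and measured community compositions
#'
#' Hierarchical log-additive Gaussian model with softmax normalization. Each
#' taxon receives a global log abundance (standard normal) plus independent
#' perturbations at each design level: subject, week-within-subject,
#' day-within-subject, extraction, and library prep, with standard deviations
#' taken from the config. The latent (biological) profile of a subject-day is
#' the softmax of the global + subject + week + day terms; measured profiles
#' add the technical terms. Both modalities share all biological and
#' technical terms; the amplicon modality additionally carries a fixed
#' per-taxon log bias and extra library-level log noise before
#' renormalization, emulating amplification bias.
#'
#' @param config a [simulation_config()].
#' @param design output of [simulate_design()] for the same config.
#' @return list with elements
#'   \describe{
#'     \item{latent}{taxa x biological-unit matrix of latent compositions,
#'       columns named `subject_d<day>`; each column sums to 1.}
#'     \item{compositions}{taxa x sample matrix of measured compositions for
#'       every design row (both modalities); each column sums to 1.}
#'     \item{taxa}{taxon ids.}
#'   }
#' @export
simulate_profiles <- function(config, design) {
  validate_config(config)
  taxa <- sprintf("T%03d", seq_len(config$n_taxa))
  nt <- config$n_taxa

  subjects <- sprintf("S%d", seq_len(config$n_subjects))
  units_sw <- unique(design[, c("subject", "week")])
  units_sw <- units_sw[order(units_sw$subject, units_sw$week), , drop = FALSE]
  units_sd <- unique(design[, c("subject", "day")])
  units_sd <- units_sd[order(units_sd$subject, units_sd$day), , drop = FALSE]
  units_e <- unique(design[, c("subject", "day", "extraction_rep")])
  units_e <- units_e[order(units_e$subject, units_e$day, units_e$extraction_rep), ,
                     drop = FALSE]
  units_l <- unique(design[, c("subject", "day", "extraction_rep", "libprep_rep")])
  units_l <- units_l[order(units_l$subject, units_l$day, units_l$extraction_rep,
                           units_l$libprep_rep), , drop = FALSE]

  draw <- function(n_units, sigma) {
    matrix(stats::rnorm(n_units * nt, sd = max(sigma, 0)), nrow = nt)
  }

  eff <- with_seed(config$seed, {
    list(
      global = stats::rnorm(nt),
      subject = draw(length(subjects), config$sigma_subject),
      week = draw(nrow(units_sw), config$sigma_week),
      day = draw(nrow(units_sd), config$sigma_day),
      extraction = draw(nrow(units_e), config$sigma_extraction),
      libprep = draw(nrow(units_l), config$sigma_libprep),
      amp_bias = stats::rnorm(nt, sd = max(config$amplicon_bias_sigma, 0)),
      amp_extra = draw(nrow(units_l), config$amplicon_extra_libprep_sigma)
    )
  })

  key_sw <- paste(units_sw$subject, units_sw$week)
  key_sd <- paste(units_sd$subject, units_sd$day)
  key_e <- paste(units_e$subject, units_e$day, units_e$extraction_rep)
  key_l <- paste(units_l$subject, units_l$day, units_l$extraction_rep,
                 units_l$libprep_rep)

  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

  # latent biological profiles, one per subject-day
  latent <- vapply(seq_len(nrow(units_sd)), function(i) {
    s <- match(units_sd$subject[i], subjects)
    w <- match(paste(units_sd$subject[i], (units_sd$day[i] - 1L) %/% 7L + 1L),
               key_sw)
    softmax(eff$global + eff$subject[, s] + eff$week[, w] + eff$day[, i])
  }, numeric(nt))
  colnames(latent) <- paste0(units_sd$subject, "_d", units_sd$day)
  rownames(latent) <- taxa

  compositions <- vapply(seq_len(nrow(design)), function(i) {
    r <- design[i, ]
    s <- match(r$subject, subjects)
    w <- match(paste(r$subject, r$week), key_sw)
    d <- match(paste(r$subject, r$day), key_sd)
    e <- match(paste(r$subject, r$day, r$extraction_rep), key_e)
    l <- match(paste(r$subject, r$day, r$extraction_rep, r$libprep_rep), key_l)
    z <- eff$global + eff$subject[, s] + eff$week[, w] + eff$day[, d] +
      eff$extraction[, e] + eff$libprep[, l]
    if (r$modality == "AMPLICON")
      z <- z + eff$amp_bias + eff$amp_extra[, l]
    softmax(z)
  }, numeric(nt))
  colnames(compositions) <- design$sample_id
  rownames(compositions) <- taxa

  list(latent = latent, compositions = compositions, taxa = taxa)
}

#' Draw sequencing counts from a composition
#'
#' Multinomial sampling of `depth` reads from a relative-abundance vector.
#'
#' @param composition nonnegative numeric vector summing to 1.
#' @param depth positive integer number of reads.
#' @param seed optional seed for reproducibility.
#' @return integer count vector summing to `depth`, names preserved.
#' @export
sample_counts <- function(composition, depth, seed = NULL) {
  if (any(composition < 0)) abort("composition entries must be nonnegative")
  if (abs(sum(composition) - 1) > 1e-6)
    abort("composition must sum to 1 (got %.6g)", sum(composition))
  if (!is_count_scalar(depth) || depth <= 0) abort("depth must be a positive integer")
  counts <- with_seed(seed, {
    drop(stats::rmultinom(1L, size = depth, prob = composition))
  })
  names(counts) <- names(composition)
  counts
}

#' Draw count tables for every sample in a design
#'
#' @param profiles output of [simulate_profiles()].
#' @param design the design data.frame.
#' @param config the config (read depths per modality).
#' @param seed optional seed; defaults to `config$seed + 1`.
#' @return taxa x sample integer matrix covering all design rows.
#' @export
simulate_count_tables <- function(profiles, design, config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 1L
  depth <- ifelse(design$modality == "SHOTGUN",
                  config$read_depth_shotgun, config$read_depth_amplicon)
  with_seed(seed, {
    counts <- vapply(seq_len(nrow(design)), function(i) {
      drop(stats::rmultinom(1L, size = depth[i],
                            prob = profiles$compositions[, design$sample_id[i]]))
    }, numeric(config$n_taxa))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(profiles$taxa, design$sample_id)
    counts
  })
}
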