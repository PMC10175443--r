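#' Simulation configuration for the nested-replicate study design
#'
#' Builds and validates the configuration driving the community simulator.
#' The defaults emulate the study design the package targets: 5 subjects
#' sampled on days 1, 2, 8 and 9, two DNA-extraction replicates per sample
#' and two library-prep/sequencing replicates per extraction, measured with
#' both an amplicon-like and a shotgun-like modality (80 samples each).
#'
#' The `sigma_*` parameters are standard deviations of independent Gaussian
#' perturbations added on the log-abundance scale at each level of the
#' design hierarchy; compositions are recovered by softmax. The defaults
#' order subject > week = day > extraction = libprep, i.e. between-subject
#' variation dominates temporal variation, which dominates technical
#' variation. The amplicon modality carries a fixed per-taxon log bias
#' (`amplicon_bias_sigma`, the amplification bias that is consistent within
#' a study) plus extra library-level noise (`amplicon_extra_libprep_sigma`)
#' on top of the shared technical components.
#'
#' @param n_subjects number of subjects.
#' @param days sampling days (ascending); the default spans two weeks with
#'   consecutive-day pairs (1,2) and (8,9).
#' @param n_extractions DNA-extraction replicates per subject-day sample.
#' @param n_libpreps library-prep/sequencing replicates per extraction.
#' @param n_taxa number of taxa (one reference genome each).
#' @param sigma_subject,sigma_week,sigma_day,sigma_extraction,sigma_libprep
#'   standard deviations (log scale) of the per-level perturbations.
#' @param amplicon_bias_sigma sd of the fixed per-taxon amplicon log bias.
#' @param amplicon_extra_libprep_sigma sd of the extra amplicon library-level
#'   log noise.
#' @param p_species_16s probability an amplicon feature is resolved to
#'   species (remaining features stop at genus).
#' @param read_depth_shotgun,read_depth_amplicon reads per sample.
#' @param genome_length_range min/max simulated genome length (bp).
#' @param unique_fraction fraction of each genome marked as unique regions.
#' @param n_kos_per_genome gene (KEGG-ortholog) annotations per genome.
#' @param p_tie probability a shotgun read is emitted with a tie set spanning
#'   all genomes of its taxon's genus (exercises LCA assignment).
#' @param seed integer root seed for all randomness.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 5L,
                              days = c(1L, 2L, 8L, 9L),
                              n_extractions = 2L,
                              n_libpreps = 2L,
                              n_taxa = 50L,
                              sigma_subject = 1.0,
                              sigma_week = 0.4,
                              sigma_day = 0.4,
                              sigma_extraction = 0.1,
                              sigma_libprep = 0.1,
                              amplicon_bias_sigma = 0.5,
                              amplicon_extra_libprep_sigma = 0.2,
                              p_species_16s = 0.3,
                              read_depth_shotgun = 10000L,
                              read_depth_amplicon = 10000L,
                              genome_length_range = c(100000L, 1000000L),
                              unique_fraction = 0.1,
                              n_kos_per_genome = 8L,
                              p_tie = 0.3,
                              seed = 42L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    days = as.integer(days),
    n_extractions = as.integer(n_extractions),
    n_libpreps = as.integer(n_libpreps),
    n_taxa = as.integer(n_taxa),
    sigma_subject = as.numeric(sigma_subject),
    sigma_week = as.numeric(sigma_week),
    sigma_day = as.numeric(sigma_day),
    sigma_extraction = as.numeric(sigma_extraction),
    sigma_libprep = as.numeric(sigma_libprep),
    amplicon_bias_sigma = as.numeric(amplicon_bias_sigma),
    amplicon_extra_libprep_sigma = as.numeric(amplicon_extra_libprep_sigma),
    p_species_16s = as.numeric(p_species_16s),
    read_depth_shotgun = as.integer(read_depth_shotgun),
    read_depth_amplicon = as.integer(read_depth_amplicon),
    genome_length_range = as.integer(genome_length_range),
    unique_fraction = as.numeric(unique_fraction),
    n_kos_per_genome = as.integer(n_kos_per_genome),
    p_tie = as.numeric(p_tie),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  c <- config
  if (c$n_subjects < 1L) abort("n_subjects must be >= 1")
  if (length(c$days) < 1L || anyNA(c$days)) abort("days must be non-empty")
  if (is.unsorted(c$days, strictly = TRUE)) abort("days must be sorted ascending")
  if (c$n_extractions < 1L || c$n_libpreps < 1L)
    abort("replicate counts must be >= 1")
  if (c$n_taxa < 2L) abort("n_taxa must be >= 2")
  sig <- c[c("sigma_subject", "sigma_week", "sigma_day", "sigma_extraction",
             "sigma_libprep", "amplicon_bias_sigma",
             "amplicon_extra_libprep_sigma")]
  if (any(unlist(sig) < 0)) abort("all sigmas must be >= 0")
  if (c$p_species_16s < 0 || c$p_species_16s > 1)
    abort("p_species_16s must be in [0, 1]")
  if (c$p_tie < 0 || c$p_tie > 1) abort("p_tie must be in [0, 1]")
  if (c$read_depth_shotgun <= 0L || c$read_depth_amplicon <= 0L)
    abort("read depths must be > 0")
  if (length(c$genome_length_range) != 2L ||
      c$genome_length_range[1] > c$genome_length_range[2])
    abort("genome_length_range must be (min, max) with min <= max")
  if (c$genome_length_range[1] < 100L)
    abort("minimum genome length must be >= read length (100 bp)")
  if (c$unique_fraction <= 0 || c$unique_fraction > 1)
    abort("unique_fraction must be in (0, 1]")
  if (c$n_kos_per_genome < 1L) abort("n_kos_per_genome must be >= 1")
  invisible(config)
}

#' Read a simulation config from JSON
#'
#' Missing fields take the defaults of [simulation_config()].
#'
#' @param path JSON file path.
#' @return a `"simulation_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L)
    abort("unknown config fields: %s", paste(extra, collapse = ", "))
  do.call(simulation_config, raw)
}

#' Write a simulation config as JSON
#'
#' @param config a `"simulation_config"`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:",
      sprintf("%d subjects x days {%s} x %d extractions x %d libpreps, %d taxa",
              x$n_subjects, paste(x$days, collapse = ","),
              x$n_extractions, x$n_libpreps, x$n_taxa), "\n")
  cat(sprintf("  sigmas: subject %.3g week %.3g day %.3g extraction %.3g libprep %.3g\n",
              x$sigma_subject, x$sigma_week, x$sigma_day,
              x$sigma_extraction, x$sigma_libprep))
  cat(sprintf("  amplicon: bias %.3g extra-libprep %.3g p_species %.3g\n",
              x$amplicon_bias_sigma, x$amplicon_extra_libprep_sigma,
              x$p_species_16s))
  cat(sprintf("  depths: shotgun %d amplicon %d; seed %d\n",
              x$read_depth_shotgun, x$read_depth_amplicon, x$seed))
  invisible(x)
}
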