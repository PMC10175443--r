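# End-to-end orchestration: simulate -> profile -> diversity -> partition ->
# stats, all file-backed so each stage can also be run on user-supplied
# tables in the same TSV formats. One root seed drives every stage.

stat_to_list <- function(x) {
  x[c("method", "statistic", "df", "r_squared", "p_value", "p_adjusted",
      "n_perm", "comparison")]
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes the five stages in order and writes every intermediate and
#' final artifact under `out_dir`:
#' \describe{
#'   \item{simulate}{design metadata, reference db, latent profiles, count
#'     tables, shotgun hit table, amplicon ASV table.}
#'   \item{profile}{filtered OTU relative abundances, per-read-LCA taxa
#'     table, KO/enzyme tables, amplicon taxonomy-collapsed table, filter
#'     log (JSON lines).}
#'   \item{diversity}{rarefied taxa tables, alpha diversity, Bray-Curtis
#'     matrices (taxa per modality + shotgun enzymes), PCoA coordinates.}
#'   \item{partition}{variation records per modality, genus concordance,
#'     resolution summaries.}
#'   \item{stats}{PERMANOVA and dispersion tests by subject, Kruskal-Wallis
#'     + Dunn on alpha diversity and on variation categories, two-way ANOVA
#'     and t-tests comparing technical variation across modalities.}
#' }
#' Rerunning with the same config and seed reproduces identical outputs.
#'
#' @param config a [simulation_config()] or path to a JSON config.
#' @param out_dir output directory (created if needed).
#' @param seed root seed; defaults to `config$seed`.
#' @param n_perm permutations for the permutation tests.
#' @return the run manifest (invisibly also written as `manifest.json`):
#'   config snapshot, seed, package version, per-stage status, outputs with
#'   md5 hashes, timestamps.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, n_perm = 999L) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config = unclass(config), seed = config$seed,
                   version = as.character(utils::packageVersion("microvar")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  env <- new.env(parent = emptyenv())

  record <- function(name, status, outputs = character(0)) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, status = status,
           outputs = as.list(hash_files(outputs)))
  }
  finish <- function() {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      record(name, "failed")
      finish()
      abort("stage '%s' failed: %s", name, conditionMessage(res))
    }
    record(name, "completed", res)
  }

  run_stage("simulate", function() stage_simulate(config, out_dir, env))
  run_stage("profile", function() stage_profile(config, out_dir, env))
  run_stage("diversity", function() stage_diversity(config, out_dir, env))
  run_stage("partition", function() stage_partition(config, out_dir, env))
  run_stage("stats", function() stage_stats(config, out_dir, env, n_perm))

  finish()
  invisible(manifest)
}

stage_simulate <- function(config, out_dir, env) {
  design <- simulate_design(config)
  refdb <- build_reference_db(config)
  profiles <- simulate_profiles(config, design)
  counts <- simulate_count_tables(profiles, design, config)
  sh <- design$sample_id[design$modality == "SHOTGUN"]
  am <- design$sample_id[design$modality == "AMPLICON"]
  hits <- generate_hit_table(counts[, sh, drop = FALSE], refdb, config)
  asv <- simulate_asv_table(counts[, am, drop = FALSE], refdb, config)

  env$design <- design; env$refdb <- refdb; env$profiles <- profiles
  env$counts <- counts; env$hits <- hits; env$asv <- asv

  paths <- c(
    write_metadata(design, file.path(out_dir, "metadata.tsv")),
    write_feature_table(profiles$latent, file.path(out_dir, "latent_profiles.tsv"),
                        id_column = "taxon_id"),
    write_feature_table(counts[, sh, drop = FALSE],
                        file.path(out_dir, "counts_shotgun.tsv"), "taxon_id"),
    write_hit_table(hits, file.path(out_dir, "hits.tsv")),
    write_feature_table(asv$table, file.path(out_dir, "asv_table.tsv"), "asv_id"),
    write_tsv(data.frame(asv_id = names(asv$lineages),
                         lineage = unname(asv$lineages)),
              file.path(out_dir, "asv_lineages.tsv"))
  )
  db <- write_reference_db(refdb, file.path(out_dir, "refdb"))
  c(paths, file.path(db, c("genomes.tsv", "genes.tsv", "ko2enzyme.tsv")))
}

stage_profile <- function(config, out_dir, env) {
  prof <- profile_hits(env$hits, env$refdb,
                       min_sample_depth = min(10000L, config$read_depth_shotgun))
  amp_taxa <- collapse_asvs_by_taxonomy(env$asv$table, env$asv$lineages)
  env$prof <- prof; env$amp_taxa <- amp_taxa

  log_path <- file.path(out_dir, "filter_log.jsonl")
  con <- file(log_path, "w")
  fl <- prof$filter_log
  if (nrow(fl) > 0)
    for (i in seq_len(nrow(fl)))
      writeLines(jsonlite::toJSON(as.list(fl[i, ]), auto_unbox = TRUE), con)
  close(con)

  c(write_feature_table(prof$otu_relabund,
                        file.path(out_dir, "otu_relabund_shotgun.tsv"), "otu_id"),
    write_feature_table(prof$taxa_counts,
                        file.path(out_dir, "taxa_counts_shotgun.tsv"), "lineage"),
    write_feature_table(prof$functions$ko,
                        file.path(out_dir, "ko_relabund_shotgun.tsv"), "ko_id"),
    write_feature_table(prof$functions$enzyme,
                        file.path(out_dir, "enzyme_relabund_shotgun.tsv"),
                        "enzyme_id"),
    write_feature_table(amp_taxa,
                        file.path(out_dir, "taxa_counts_amplicon.tsv"), "lineage"),
    log_path)
}

stage_diversity <- function(config, out_dir, env) {
  paths <- character(0)
  env$rarefied <- list(); env$bc <- list()
  tables <- list(SHOTGUN = env$prof$taxa_counts, AMPLICON = env$amp_taxa)
  for (mod in names(tables)) {
    tab <- tables[[mod]]
    rar <- rarefy_table(tab, seed = config$seed + 5L)
    rel <- to_relative_abundance(rar)
    D <- bray_curtis_matrix(rel)
    alpha <- alpha_diversity_table(rar)
    pc <- pcoa(D)
    env$rarefied[[mod]] <- rar; env$bc[[mod]] <- D
    tag <- tolower(mod)
    coords <- data.frame(sample_id = rownames(pc$coordinates),
                         pc$coordinates[, seq_len(min(5L, ncol(pc$coordinates))),
                                        drop = FALSE], check.names = FALSE)
    sidecar <- file.path(out_dir, sprintf("pcoa_%s.json", tag))
    jsonlite::write_json(list(eigenvalues = pc$eigenvalues,
                              proportion_explained = pc$proportion_explained),
                         sidecar, digits = NA)
    paths <- c(paths,
               write_tsv(alpha, file.path(out_dir, sprintf("alpha_%s.tsv", tag))),
               write_distance_matrix(D, file.path(out_dir,
                                                  sprintf("bray_curtis_%s.tsv", tag))),
               write_tsv(coords, file.path(out_dir, sprintf("pcoa_%s.tsv", tag))),
               sidecar)
  }
  # functional beta diversity for the shotgun path
  enz <- env$prof$functions$enzyme_counts
  if (nrow(enz) > 0) {
    enz_rel <- to_relative_abundance(rarefy_table(enz, seed = config$seed + 5L))
    env$bc$ENZYME <- bray_curtis_matrix(enz_rel)
    paths <- c(paths, write_distance_matrix(
      env$bc$ENZYME, file.path(out_dir, "bray_curtis_enzyme_shotgun.tsv")))
  }
  paths
}

stage_partition <- function(config, out_dir, env) {
  paths <- character(0)
  env$records <- list()
  for (mod in c("SHOTGUN", "AMPLICON")) {
    rec <- partition_dissimilarities(env$bc[[mod]], env$design)
    env$records[[mod]] <- rec
    paths <- c(paths, write_variation_records(
      rec, file.path(out_dir, sprintf("variation_%s.tsv", tolower(mod)))))
  }
  conc <- genus_concordance(
    to_relative_abundance(env$amp_taxa),
    to_relative_abundance(env$prof$taxa_counts),
    env$design, per_sample = TRUE)
  res <- list(
    concordance = conc,
    resolution = list(
      SHOTGUN = as.list(resolution_summary(env$prof$taxa_counts)),
      AMPLICON = as.list(resolution_summary(env$amp_taxa))
    ),
    top_taxa = list(
      SHOTGUN = top_taxa(to_relative_abundance(env$prof$taxa_counts)),
      AMPLICON = top_taxa(to_relative_abundance(env$amp_taxa))
    )
  )
  rp <- file.path(out_dir, "concordance_resolution.json")
  jsonlite::write_json(res, rp, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  c(paths, rp)
}

stage_stats <- function(config, out_dir, env, n_perm) {
  seed <- config$seed
  out <- list()
  for (mod in c("SHOTGUN", "AMPLICON")) {
    D <- env$bc[[mod]]
    meta <- env$design[match(rownames(D), env$design$sample_id), ]
    shannon <- apply(env$rarefied[[mod]], 2L, alpha_diversity, metric = "shannon")
    rec <- env$records[[mod]]
    out[[mod]] <- list(
      permanova_subject = stat_to_list(
        permanova(D, meta$subject, n_perm = n_perm, seed = seed + 6L)),
      betadisper_subject = stat_to_list(
        betadisper_test(D, meta$subject, n_perm = n_perm, seed = seed + 7L)),
      kruskal_alpha_subject = stat_to_list(
        kruskal_wallis(shannon, meta$subject)),
      dunn_alpha_subject = dunn_posthoc(shannon, meta$subject),
      kruskal_variation = stat_to_list(
        kruskal_wallis(rec$dissimilarity, rec$category)),
      dunn_variation = dunn_posthoc(rec$dissimilarity, rec$category),
      category_medians = as.list(tapply(rec$dissimilarity, rec$category,
                                        stats::median))
    )
  }
  tech <- do.call(rbind, lapply(env$records, function(r)
    r[r$category %in% c("LIBPREP", "EXTRACTION"), ]))
  aov2 <- two_way_anova(tech$dissimilarity, tech$modality, tech$category)
  tt <- lapply(c(LIBPREP = "LIBPREP", EXTRACTION = "EXTRACTION"), function(cat) {
    a <- tech$dissimilarity[tech$modality == "AMPLICON" & tech$category == cat]
    s <- tech$dissimilarity[tech$modality == "SHOTGUN" & tech$category == cat]
    stat_to_list(t_test(a, s))
  })
  out$cross_modality <- list(
    two_way_anova = list(modality = stat_to_list(aov2$factor_a),
                         category = stat_to_list(aov2$factor_b)),
    t_tests = tt
  )
  sp <- file.path(out_dir, "stats.json")
  jsonlite::write_json(out, sp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  flat <- do.call(rbind, lapply(c("SHOTGUN", "AMPLICON"), function(mod) {
    s <- out[[mod]]
    data.frame(
      modality = mod,
      test = c("permanova_subject", "betadisper_subject",
               "kruskal_alpha_subject", "kruskal_variation"),
      statistic = c(s$permanova_subject$statistic,
                    s$betadisper_subject$statistic,
                    s$kruskal_alpha_subject$statistic,
                    s$kruskal_variation$statistic),
      p_value = c(s$permanova_subject$p_value, s$betadisper_subject$p_value,
                  s$kruskal_alpha_subject$p_value,
                  s$kruskal_variation$p_value),
      stringsAsFactors = FALSE)
  }))
  c(sp, write_tsv(flat, file.path(out_dir, "stats_summary.tsv")))
}
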