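test_that("design enumeration matches the nested study layout", {
  design <- simulate_design(simulation_config())
  expect_equal(nrow(design), 160L)
  expect_equal(sum(design$modality == "AMPLICON"), 80L)
  expect_equal(sum(design$modality == "SHOTGUN"), 80L)
  expect_false(anyDuplicated(design$sample_id) > 0)
  expect_true(all(design$week[design$day <= 2] == 1L))
  expect_true(all(design$week[design$day >= 8] == 2L))

  tiny <- simulate_design(simulation_config(n_subjects = 1, days = 1,
                                            n_extractions = 1, n_libpreps = 1))
  expect_equal(nrow(tiny), 2L)  # one per modality

  d1 <- simulate_design(simulation_config())
  d2 <- simulate_design(simulation_config())
  expect_identical(d1$sample_id, d2$sample_id)

  expect_error(simulation_config(n_extractions = 0), "replicate")
  expect_error(simulation_config(days = c(2, 1)), "ascending")
})

test_that("zero-variance simulation collapses to a single composition", {
  cfg <- simulation_config(n_subjects = 2, n_taxa = 6,
                           sigma_subject = 0, sigma_week = 0, sigma_day = 0,
                           sigma_extraction = 0, sigma_libprep = 0,
                           amplicon_bias_sigma = 0,
                           amplicon_extra_libprep_sigma = 0)
  design <- simulate_design(cfg)
  prof <- simulate_profiles(cfg, design)
  expect_true(all(abs(colSums(prof$compositions) - 1) < 1e-9))
  ref <- prof$compositions[, 1]
  expect_true(all(apply(prof$compositions, 2, function(x)
    max(abs(x - ref))) < 1e-12))
})

test_that("amplicon bias perturbs only the amplicon modality", {
  cfg <- simulation_config(n_subjects = 1, days = 1, n_extractions = 1,
                           n_libpreps = 1, n_taxa = 6,
                           sigma_subject = 0, sigma_week = 0, sigma_day = 0,
                           sigma_extraction = 0, sigma_libprep = 0,
                           amplicon_bias_sigma = 1,
                           amplicon_extra_libprep_sigma = 0)
  design <- simulate_design(cfg)
  prof <- simulate_profiles(cfg, design)
  sh <- prof$compositions[, design$sample_id[design$modality == "SHOTGUN"]]
  am <- prof$compositions[, design$sample_id[design$modality == "AMPLICON"]]
  expect_equal(unname(sh), unname(prof$latent[, 1]), tolerance = 1e-12)
  expect_gt(max(abs(am - sh)), 1e-3)
})

test_that("between-subject dissimilarity dominates when subject variance dominates", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(n_subjects = 3, days = c(1, 2),
                             n_extractions = 1, n_libpreps = 1, n_taxa = 20,
                             sigma_subject = 2, sigma_week = 0.1,
                             sigma_day = 0.1, sigma_extraction = 0,
                             sigma_libprep = 0, seed = s)
    design <- simulate_design(cfg)
    design <- design[design$modality == "SHOTGUN", ]
    prof <- simulate_profiles(cfg, design)
    D <- bray_curtis_matrix(prof$compositions[, design$sample_id])
    same <- outer(design$subject, design$subject, "==")
    ut <- upper.tri(D)
    if (mean(D[ut & !same]) > mean(D[ut & same])) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("within-category dissimilarity grows with its variance component", {
  mean_libprep_bc <- function(sigma) {
    vals <- vapply(1:20, function(s) {
      cfg <- simulation_config(n_subjects = 2, days = 1, n_taxa = 15,
                               sigma_subject = 0.5, sigma_week = 0,
                               sigma_day = 0, sigma_extraction = 0.05,
                               sigma_libprep = sigma, seed = s)
      design <- simulate_design(cfg)
      design <- design[design$modality == "SHOTGUN", ]
      prof <- simulate_profiles(cfg, design)
      rec <- partition_dissimilarities(
        bray_curtis_matrix(prof$compositions[, design$sample_id]), design)
      mean(rec$dissimilarity[rec$category == "LIBPREP"])
    }, numeric(1))
    mean(vals)
  }
  m <- vapply(c(0, 0.3, 0.8), mean_libprep_bc, numeric(1))
  expect_true(all(diff(m) > 0))
  expect_lt(m[1], 1e-9)  # no libprep noise -> identical compositions
})

test_that("technical-replicate dissimilarity vanishes without technical noise at depth", {
  cfg <- simulation_config(n_subjects = 2, days = 1, n_taxa = 30,
                           sigma_extraction = 0, sigma_libprep = 0,
                           amplicon_bias_sigma = 0,
                           amplicon_extra_libprep_sigma = 0,
                           read_depth_shotgun = 1000000L,
                           read_depth_amplicon = 1000000L, seed = 7)
  rec <- simulate_variation_records(cfg)
  tech <- rec$dissimilarity[rec$category %in% c("LIBPREP", "EXTRACTION")]
  expect_lt(median(tech), 0.02)
})

test_that("multinomial count sampling behaves", {
  expect_equal(unname(sample_counts(c(1, 0, 0), 100, seed = 1)), c(100, 0, 0))
  x <- sample_counts(c(0.5, 0.5), 1e6, seed = 2)
  expect_equal(sum(x), 1e6)
  sd1 <- sqrt(1e6 * 0.25)
  expect_true(all(abs(x - 5e5) < 5 * sd1))
  expect_error(sample_counts(c(0.5, 0.5), 0), "depth")
  expect_error(sample_counts(c(-0.1, 1.1), 10), "nonnegative")
})

test_that("reference database honors its configuration", {
  cfg <- simulation_config(n_taxa = 10, n_kos_per_genome = 5)
  db <- build_reference_db(cfg)
  expect_equal(nrow(db$genes), 50L)
  expect_gte(length(unique(lineage_rank_value(db$genomes$lineage, "phylum"))), 2L)

  full <- build_reference_db(simulation_config(n_taxa = 4, unique_fraction = 1))
  iv <- t(vapply(full$genomes$unique_intervals,
                 function(x) microvar:::parse_intervals(x)[1, ], numeric(2)))
  expect_equal(unname(iv[, 2] - iv[, 1]), full$genomes$length)

  d <- tempfile(); dir.create(d)
  write_reference_db(build_reference_db(cfg), file.path(d, "a"))
  write_reference_db(build_reference_db(cfg), file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a", "genomes.tsv")),
                   readLines(file.path(d, "b", "genomes.tsv")))

  expect_error(simulation_config(genome_length_range = c(50, 1000)),
               "read length")
})

test_that("hit tables respect tie probability and depth conservation", {
  cfg <- small_config(p_tie = 0)
  db <- build_reference_db(cfg)
  counts <- matrix(c(5L, 3L, 0L, 2L), 4, 1,
                   dimnames = list(db$genomes$taxon_id[1:4], "s1"))
  h0 <- generate_hit_table(counts, db, cfg)
  expect_equal(nrow(h0), 10L)
  expect_true(all(!grepl(";", h0$tied_genome_ids)))

  cfg1 <- small_config(p_tie = 1)
  h1 <- generate_hit_table(counts, db, cfg1)
  # taxa are paired two-per-genus, so every tie set has exactly 2 genomes
  expect_true(all(lengths(strsplit(h1$tied_genome_ids, ";")) == 2L))

  empty <- generate_hit_table(counts * 0L, db, cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- small_config()
  design <- simulate_design(cfg)
  prof1 <- simulate_profiles(cfg, design)
  prof2 <- simulate_profiles(cfg, design)
  expect_identical(prof1, prof2)
  c1 <- simulate_count_tables(prof1, design, cfg)
  c2 <- simulate_count_tables(prof2, design, cfg)
  expect_identical(c1, c2)
  sh <- design$sample_id[design$modality == "SHOTGUN"][1:4]
  expect_identical(generate_hit_table(c1[, sh], build_reference_db(cfg), cfg),
                   generate_hit_table(c2[, sh], build_reference_db(cfg), cfg))
})
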