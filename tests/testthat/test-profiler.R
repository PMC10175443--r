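lin <- function(...) lineage_make(c(...))

test_that("capitalist tie-breaking minimizes distinct OTUs on fixtures", {
  hits <- data.frame(sample_id = "s", read_id = c("r1", "r2", "r3"),
                     tied_genome_ids = c("G1;G2", "G1", "G1;G3"),
                     position = 0L, gene_id = NA_character_)
  res <- resolve_ties_capitalist(hits)
  expect_equal(res$chosen_genome, c("G1", "G1", "G1"))
  expect_equal(length(unique(res$chosen_genome)),
               min_unique_otus_exhaustive(strsplit(hits$tied_genome_ids, ";")))

  hits2 <- data.frame(sample_id = "s", read_id = c("r1", "r2"),
                      tied_genome_ids = c("G1;G2", "G2;G3"),
                      position = 0L, gene_id = NA_character_)
  expect_equal(resolve_ties_capitalist(hits2)$chosen_genome, c("G2", "G2"))

  single <- data.frame(sample_id = "s", read_id = "r1",
                       tied_genome_ids = "G5", position = 0L,
                       gene_id = NA_character_)
  expect_equal(resolve_ties_capitalist(single)$chosen_genome, "G5")
  expect_error(resolve_ties_capitalist(
    data.frame(sample_id = "s", read_id = "r", tied_genome_ids = "",
               position = 0L, gene_id = NA_character_)), "empty tie set")
})

test_that("greedy unique-OTU count matches the exhaustive minimum on small random instances", {
  set.seed(11)
  for (trial in 1:25) {
    genomes <- paste0("G", 1:6)
    n_reads <- sample(3:12, 1)
    ties <- replicate(n_reads, sample(genomes, sample(1:3, 1)),
                      simplify = FALSE)
    hits <- data.frame(sample_id = "s", read_id = paste0("r", seq_len(n_reads)),
                       tied_genome_ids = vapply(ties, paste, "", collapse = ";"),
                       position = 0L, gene_id = NA_character_)
    greedy <- length(unique(resolve_ties_capitalist(hits)$chosen_genome))
    opt <- min_unique_otus_exhaustive(ties)
    expect_lte(greedy, opt + 1L)
    expect_gte(greedy, opt)
  }
})

test_that("LCA consensus threshold is inclusive and descends ranks correctly", {
  db <- make_refdb(c(
    G1 = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "X"),
    G2 = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "X"),
    G3 = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "X"),
    G4 = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "X"),
    G5 = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "Y")))
  # 4/5 share species X: exactly at the 80% boundary, inclusive
  out <- assign_lineage(paste0("G", 1:5), db)
  expect_equal(lineage_rank_value(out, "species"), "X")

  strains <- make_refdb(c(
    A = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "E. coli", "K12"),
    B = lin("Bacteria", "P", "C", "O", "F", "Escherichia", "E. coli", "O157")))
  out2 <- assign_lineage(c("A", "B"), strains)
  expect_equal(lineage_depth(out2), 7L)
  expect_equal(lineage_rank_value(out2, "species"), "E. coli")

  mixed <- make_refdb(c(
    G1 = lin("Bacteria", "P", "C", "O", "Enterobacteriaceae", "Escherichia", "X"),
    G2 = lin("Bacteria", "P", "C", "O", "Enterobacteriaceae", "Escherichia", "Y"),
    G3 = lin("Bacteria", "P", "C", "O", "Enterobacteriaceae", "Salmonella", "Z")))
  out3 <- assign_lineage(c("G1", "G2", "G3"), mixed)
  expect_equal(lineage_depth(out3), 5L)  # genus consensus 2/3 < 0.8 -> family
  expect_equal(lineage_rank_value(out3, "family"), "Enterobacteriaceae")

  expect_error(assign_lineage("GX", db), "missing")
})

test_that("lowering the LCA threshold never yields a shallower lineage", {
  set.seed(5)
  cfg <- small_config()
  db <- build_reference_db(cfg)
  for (trial in 1:20) {
    ts <- sample(db$genomes$genome_id, sample(2:6, 1))
    depths <- vapply(c(0.9, 0.8, 0.6, 0.4),
                     function(th) lineage_depth(assign_lineage(ts, db, th)),
                     integer(1))
    expect_true(all(diff(depths) >= 0))
  }
})

test_that("tabulation counts reads and computes union coverage", {
  db <- make_refdb(c(G1 = lin("Bacteria")), lengths = 10000L,
                   unique_intervals = "0-1000")
  one <- data.frame(sample_id = "s1", read_id = "r1", tied_genome_ids = "G1",
                    position = 0L, gene_id = NA_character_,
                    chosen_genome = "G1")
  otu <- tabulate_assignments(one, db)
  expect_equal(otu$coverage$genome_cov, 0.01)
  expect_equal(otu$coverage$unique_cov, 0.1)

  two <- rbind(one, transform(one, read_id = "r2"))  # fully overlapping
  otu2 <- tabulate_assignments(two, db)
  expect_equal(otu2$coverage$genome_cov, 0.01)
  expect_equal(otu2$counts["G1", "s1"], 2L)

  expect_error(tabulate_assignments(transform(one, position = 9950L), db),
               "outside genome")
})

test_that("assigned counts conserve hit rows per sample", {
  cfg <- small_config(p_tie = 0.5)
  db <- build_reference_db(cfg)
  counts <- matrix(c(50L, 30L, 20L, 10L, 40L, 60L), 3, 2,
                   dimnames = list(db$genomes$taxon_id[1:3], c("s1", "s2")))
  hits <- generate_hit_table(counts, db, cfg)
  otu <- tabulate_assignments(resolve_ties_capitalist(hits), db)
  expect_equal(as.numeric(colSums(otu$counts)[c("s1", "s2")]),
               as.numeric(table(hits$sample_id)[c("s1", "s2")]))
})

test_that("genome-length normalization rescales to the per-sample mean length", {
  db <- make_refdb(c(G1 = lin("Bacteria"), G2 = lin("Bacteria")),
                   lengths = c(1000000L, 2000000L))
  otu <- make_otu_profile(matrix(c(10L, 10L), 2, 1,
                                 dimnames = list(c("G1", "G2"), "s1")),
                          genome_cov = c(0.5, 0.5), unique_cov = c(0.5, 0.5))
  norm <- genome_length_normalize(otu, db)
  expect_equal(unname(norm$normalized[, 1]), c(15, 7.5))

  same <- make_refdb(c(G1 = lin("Bacteria"), G2 = lin("Bacteria")),
                     lengths = c(1000L, 1000L))
  norm2 <- genome_length_normalize(otu, same)
  expect_equal(unname(norm2$normalized), unname(otu$counts) * 1.0)

  solo <- make_otu_profile(matrix(7L, 1, 1, dimnames = list("G1", "s1")),
                           genome_cov = 0.5, unique_cov = 0.5)
  expect_equal(unname(genome_length_normalize(solo, db)$normalized[1, 1]), 7)
})

test_that("filters drop by depth, abundance and conjunctive coverage", {
  counts <- matrix(c(9999L, 20000L, 0L, 5L), 2, 2, byrow = TRUE,
                   dimnames = list(c("G1", "G2"), c("low", "high")))
  otu <- make_otu_profile(counts, genome_cov = c(0.5, 0.005),
                          unique_cov = c(0.5, 0.0002))
  filt <- apply_filters(otu, NULL)
  expect_false("low" %in% colnames(filt$counts))      # 9,999 reads < 10,000
  expect_true("G2" %in% rownames(filt$counts))        # 0.02% unique passes
  log <- attr(filt, "filter_log")
  expect_true(any(log$entity == "low" & log$rule == "min_sample_depth"))

  # unique 0.005% AND genome 0.5% both below thresholds -> dropped
  otu2 <- make_otu_profile(matrix(c(20000L, 20000L), 2, 1,
                                  dimnames = list(c("G1", "G2"), "s1")),
                           genome_cov = c(0.5, 0.005),
                           unique_cov = c(0.5, 0.00005))
  filt2 <- apply_filters(otu2, NULL)
  expect_false("G2" %in% rownames(filt2$counts))

  # 1 read of 1e7 total is below one millionth
  otu3 <- make_otu_profile(matrix(c(9999999L, 1L), 2, 1,
                                  dimnames = list(c("G1", "G2"), "s1")),
                           genome_cov = c(0.5, 0.5), unique_cov = c(0.5, 0.5))
  filt3 <- apply_filters(otu3, NULL)
  expect_false("G2" %in% rownames(filt3$counts))
})

test_that("filtering is idempotent", {
  set.seed(3)
  counts <- matrix(rpois(40, 4000), 8, 5,
                   dimnames = list(paste0("G", 1:8), paste0("s", 1:5)))
  counts[1, ] <- 1L  # rare OTU
  storage.mode(counts) <- "integer"
  otu <- make_otu_profile(counts, genome_cov = runif(8, 0, 0.02),
                          unique_cov = runif(8, 0, 0.001))
  once <- apply_filters(otu, NULL, min_frac = 1e-3, min_sample_depth = 1000)
  twice <- apply_filters(once, NULL, min_frac = 1e-3, min_sample_depth = 1000)
  expect_equal(once$counts, twice$counts)
  expect_equal(nrow(attr(twice, "filter_log")), 0L)
})

test_that("relative abundance columns sum to one", {
  m <- matrix(c(30, 70, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  rel <- to_relative_abundance(m)
  expect_equal(unname(rel[, "s1"]), c(0.3, 0.7))
  expect_equal(unname(colSums(rel)), c(1, 1))
  expect_equal(to_relative_abundance(matrix(5, 1, 1,
                                            dimnames = list("a", "s")))[1, 1], 1)
  expect_error(to_relative_abundance(matrix(0, 2, 1,
                                            dimnames = list(c("a", "b"), "s"))),
               "all-zero")
})

test_that("function tables collapse KOs onto enzymes with full counts", {
  genes <- data.frame(genome_id = "G1",
                      gene_id = c("g1", "g2", "g3"),
                      start = c(0L, 2000L, 4000L), end = c(900L, 2900L, 4900L),
                      ko_id = c("K1", "K2", "K3"), stringsAsFactors = FALSE)
  k2e <- data.frame(ko_id = c("K1", "K2", "K3", "K3"),
                    enzyme_id = c("EC_a", "EC_a", "EC_b", "EC_c"),
                    stringsAsFactors = FALSE)
  db <- make_refdb(c(G1 = lin("Bacteria")), genes = genes, ko2enzyme = k2e)
  hits <- data.frame(
    sample_id = "s1", read_id = paste0("r", 1:10), tied_genome_ids = "G1",
    position = 0L,
    gene_id = c(rep("g1", 6), rep("g2", 4)), stringsAsFactors = FALSE)
  ft <- build_function_tables(hits, db)
  expect_equal(unname(ft$ko_counts[c("K1", "K2"), "s1"]), c(6L, 4L))
  expect_equal(unname(ft$enzyme["EC_a", "s1"]), 1.0)

  multi <- transform(hits, gene_id = "g3")  # K3 -> both EC_b and EC_c
  ft2 <- build_function_tables(multi, db)
  expect_equal(unname(ft2$enzyme_counts[c("EC_b", "EC_c"), "s1"]), c(10L, 10L))

  none <- transform(hits, gene_id = NA_character_)
  expect_warning(ft3 <- build_function_tables(none, db), "no gene hits")
  expect_equal(nrow(ft3$ko), 0L)
})

test_that("ASV collapse merges identical lineages and conserves totals", {
  tab <- matrix(c(5L, 7L, 3L, 2L, 4L, 6L), 3, 2,
                dimnames = list(c("ASV1", "ASV2", "ASV3"), c("s1", "s2")))
  lins <- c(ASV1 = "k__Bacteria;p__P;c__C;o__O;f__F;g__Bacteroides",
            ASV2 = "k__Bacteria;p__P;c__C;o__O;f__F;g__Bacteroides",
            ASV3 = "k__Bacteria;p__P;c__C;o__O;f__F;g__Prevotella")
  out <- collapse_asvs_by_taxonomy(tab, lins)
  expect_equal(nrow(out), 2L)
  expect_equal(out["k__Bacteria;p__P;c__C;o__O;f__F;g__Bacteroides", "s1"], 12L)
  expect_equal(colSums(out), colSums(tab))

  distinct <- collapse_asvs_by_taxonomy(tab[c(1, 3), ], lins[c(1, 3)])
  expect_equal(sort(unname(rowSums(distinct))), sort(unname(rowSums(tab[c(1, 3), ]))))
  expect_error(collapse_asvs_by_taxonomy(tab, lins[1:2]), "without")
})

test_that("profiled relative abundance converges to the latent composition", {
  # equal genome lengths so length normalization is the identity, p_tie = 0
  cfg <- simulation_config(n_subjects = 1, days = 1, n_extractions = 1,
                           n_libpreps = 1, n_taxa = 20, p_tie = 0,
                           genome_length_range = c(200000L, 200000L),
                           read_depth_shotgun = 1000000L,
                           sigma_subject = 0, sigma_week = 0, sigma_day = 0,
                           sigma_extraction = 0, sigma_libprep = 0, seed = 9)
  design <- simulate_design(cfg)
  design <- design[design$modality == "SHOTGUN", ]
  prof <- simulate_profiles(cfg, design)
  counts <- simulate_count_tables(prof, design, cfg)
  db <- build_reference_db(cfg)
  hits <- generate_hit_table(counts, db, cfg)
  res <- profile_hits(hits, db)
  rel <- res$otu_relabund
  latent <- prof$latent[db$genomes$taxon_id[match(rownames(rel),
                                                  db$genomes$genome_id)], 1]
  expect_lt(sum(abs(rel[, 1] - latent)), 0.02)
})
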