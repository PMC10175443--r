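# Independent oracles used across tests; these deliberately avoid the
# package's own algorithms.

# Minimum number of distinct genomes hitting every tie set, by exhaustive
# subset enumeration (hitting-set optimum for small instances).
min_unique_otus_exhaustive <- function(tie_list) {
  genomes <- sort(unique(unlist(tie_list)))
  for (k in seq_along(genomes)) {
    subsets <- utils::combn(genomes, k, simplify = FALSE)
    for (s in subsets) {
      if (all(vapply(tie_list, function(ts) any(ts %in% s), logical(1))))
        return(k)
    }
  }
  length(genomes)
}

# All permutations of 1..n, written independently of the package internals.
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# One-factor pseudo-F recomputed from the definition, for permutation
# enumeration oracles.
pseudo_f_oracle <- function(D, groups) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  ss_tot <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Minimal hand-built reference database for profiler unit tests.
make_refdb <- function(lineages, lengths = NULL, unique_intervals = NULL,
                       genes = NULL, ko2enzyme = NULL) {
  n <- length(lineages)
  ids <- names(lineages)
  if (is.null(ids)) ids <- sprintf("G%d", seq_len(n))
  if (is.null(lengths)) lengths <- rep(10000L, n)
  if (is.null(unique_intervals))
    unique_intervals <- sprintf("0-%d", lengths)
  if (is.null(genes))
    genes <- data.frame(genome_id = character(0), gene_id = character(0),
                        start = integer(0), end = integer(0),
                        ko_id = character(0), stringsAsFactors = FALSE)
  if (is.null(ko2enzyme))
    ko2enzyme <- data.frame(ko_id = character(0), enzyme_id = character(0),
                            stringsAsFactors = FALSE)
  structure(list(
    genomes = data.frame(genome_id = ids, taxon_id = paste0("T", seq_len(n)),
                         lineage = unname(lineages), length = lengths,
                         unique_intervals = unique_intervals,
                         stringsAsFactors = FALSE),
    genes = genes, ko2enzyme = ko2enzyme), class = "reference_db")
}

# Hand-built OTU profile for filter tests.
make_otu_profile <- function(counts, genome_cov, unique_cov,
                             sample_depth = colSums(counts),
                             total_assigned = sum(counts)) {
  structure(list(
    counts = counts,
    coverage = data.frame(genome_id = rownames(counts),
                          genome_cov = genome_cov, unique_cov = unique_cov,
                          stringsAsFactors = FALSE),
    lineages = stats::setNames(rep("k__Bacteria", nrow(counts)),
                               rownames(counts)),
    sample_depth = sample_depth,
    total_assigned = total_assigned,
    normalized = NULL), class = "otu_profile")
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2L, n_taxa = 10L, read_depth_shotgun = 2000L,
         read_depth_amplicon = 2000L),
    list(...))
  do.call(simulation_config, args)
}
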