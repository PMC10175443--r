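# Shotgun post-alignment profiling: capitalist tie-breaking, >=80% LCA
# taxonomic assignment, genome-length normalization,
# abundance/coverage/sample-depth filtering, and functional (KO -> enzyme)
# tables. Amplicon features only need taxonomy-collapse.

split_ties <- function(tied) strsplit(tied, ";", fixed = TRUE)

#' Resolve tied best hits by minimizing unique OTUs ("capitalist" rule)
#'
#' Each read may tie over several reference genomes. Ties are broken so that
#' the set of distinct genomes (OTUs) receiving reads is as small as
#' possible: a greedy minimum-hitting-set pass repeatedly selects the genome
#' covering the most still-unassigned reads (ties between genomes broken
#' lexicographically by genome id) and assigns those reads to it. Exact
#' minimization is NP-hard; the greedy solution matches the optimum on small
#' instances (see package tests).
#'
#' @param hits hit-table data.frame with `tied_genome_ids` semicolon-joined.
#' @return `hits` with an added `chosen_genome` column; the original tie
#'   sets are retained for lineage assignment.
#' @export
resolve_ties_capitalist <- function(hits) {
  ties <- split_ties(hits$tied_genome_ids)
  if (any(lengths(ties) == 0L) || any(hits$tied_genome_ids == ""))
    abort("empty tie set in hit table")
  chosen <- rep(NA_character_, nrow(hits))
  unresolved <- which(is.na(chosen))
  while (length(unresolved) > 0L) {
    tally <- table(unlist(ties[unresolved]))
    best <- max(tally)
    g <- sort(names(tally)[tally == best])[1]
    covered <- unresolved[vapply(ties[unresolved], function(ts) g %in% ts,
                                 logical(1))]
    chosen[covered] <- g
    unresolved <- setdiff(unresolved, covered)
  }
  hits$chosen_genome <- chosen
  hits
}

#' Lowest common ancestor of a tie set at a consensus threshold
#'
#' Returns the deepest lineage shared by at least `threshold` of the tied
#' genomes (inclusive: exactly 80% of the tie set meets the default
#' threshold), with all shallower ranks taken from that consensus.
#'
#' @param tie_set character vector of genome ids.
#' @param refdb reference database.
#' @param threshold consensus fraction in (0, 1]; default 0.8.
#' @return lineage string (possibly `""` when not even the kingdom reaches
#'   consensus).
#' @export
assign_lineage <- function(tie_set, refdb, threshold = 0.8) {
  if (length(tie_set) == 0L) abort("empty tie set")
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  idx <- match(tie_set, refdb$genomes$genome_id)
  if (anyNA(idx))
    abort("genomes missing from reference db: %s",
          paste(tie_set[is.na(idx)], collapse = ", "))
  lins <- refdb$genomes$lineage[idx]
  n <- length(lins)
  for (d in seq(max(lineage_depth(lins)), 1L)) {
    trunc <- lineage_truncate(lins, d)
    trunc <- trunc[lineage_depth(trunc) == d]
    if (length(trunc) == 0L) next
    tab <- table(trunc)
    if (max(tab) / n >= threshold - 1e-12)
      return(sort(names(tab)[tab == max(tab)])[1])
  }
  ""
}

#' Tabulate resolved read assignments into an OTU profile
#'
#' Counts reads per (chosen genome, sample) and computes per-OTU coverage
#' statistics pooled across samples: the fraction of the whole genome and of
#' its unique regions covered by the union of 100-bp read intervals.
#'
#' @param hits hit table with a `chosen_genome` column
#'   (see [resolve_ties_capitalist()]).
#' @param refdb reference database.
#' @return list of class `"otu_profile"`: `counts` (OTU x sample integer
#'   matrix; OTUs without reads are absent), `coverage` (data.frame
#'   genome_id, genome_cov, unique_cov), `lineages` (named character),
#'   `sample_depth` (named vector of raw mapped reads per sample, frozen for
#'   filtering), `total_assigned` (scalar), and `normalized` (NULL until
#'   [genome_length_normalize()]).
#' @export
tabulate_assignments <- function(hits, refdb) {
  if (is.null(hits$chosen_genome)) abort("ties must be resolved first")
  gidx <- match(hits$chosen_genome, refdb$genomes$genome_id)
  if (anyNA(gidx)) abort("chosen genome absent from reference db")
  bad <- hits$position < 0 |
    hits$position + .READ_LEN > refdb$genomes$length[gidx]
  if (any(bad))
    abort("read position outside genome for read %s", hits$read_id[which(bad)[1]])

  otus <- sort(unique(hits$chosen_genome))
  samples <- unique(hits$sample_id)
  counts <- table(factor(hits$chosen_genome, levels = otus),
                  factor(hits$sample_id, levels = samples))
  counts <- matrix(as.integer(counts), nrow = length(otus),
                   dimnames = list(otus, samples))

  ginfo <- refdb$genomes[match(otus, refdb$genomes$genome_id), ]
  cov <- vapply(seq_along(otus), function(i) {
    pos <- hits$position[hits$chosen_genome == otus[i]]
    reads <- IRanges::reduce(IRanges::IRanges(start = pos + 1L,
                                              width = .READ_LEN))
    uniq_m <- parse_intervals(ginfo$unique_intervals[i])
    uniq <- IRanges::IRanges(start = uniq_m[, "start"] + 1L,
                             end = uniq_m[, "end"])
    c(genome_cov = sum(IRanges::width(reads)) / ginfo$length[i],
      unique_cov = sum(IRanges::width(IRanges::intersect(reads, uniq))) /
        sum(IRanges::width(uniq)))
  }, numeric(2))

  structure(list(
    counts = counts,
    coverage = data.frame(genome_id = otus,
                          genome_cov = cov["genome_cov", ],
                          unique_cov = cov["unique_cov", ],
                          stringsAsFactors = FALSE),
    lineages = stats::setNames(ginfo$lineage, otus),
    sample_depth = stats::setNames(colSums(counts), samples),
    total_assigned = sum(counts),
    normalized = NULL
  ), class = "otu_profile")
}

#' @export
print.otu_profile <- function(x, ...) {
  cat(sprintf("otu_profile: %d OTUs x %d samples (%d reads assigned)\n",
              nrow(x$counts), ncol(x$counts), x$total_assigned))
  invisible(x)
}

#' Normalize OTU counts to the average genome length
#'
#' Per sample, each OTU's raw count is divided by its genome length and
#' rescaled by the mean genome length over the OTUs detected in that sample,
#' so that organisms with large genomes are not over-counted. With all
#' genome lengths equal the counts are unchanged.
#'
#' @param otu an `"otu_profile"`.
#' @param refdb reference database.
#' @return the profile with a `normalized` matrix filled in.
#' @export
genome_length_normalize <- function(otu, refdb) {
  len <- refdb$genomes$length[match(rownames(otu$counts),
                                    refdb$genomes$genome_id)]
  if (any(len <= 0)) abort("zero genome length")
  norm <- otu$counts
  storage.mode(norm) <- "double"
  for (s in seq_len(ncol(norm))) {
    det <- norm[, s] > 0
    if (!any(det)) next
    norm[, s] <- norm[, s] / len * mean(len[det])
  }
  otu$normalized <- norm
  otu
}

#' Filter an OTU profile by sample depth, abundance and coverage
#'
#' Applies, in order: (a) drop samples whose raw mapped read count is below
#' `min_sample_depth`; (b) drop OTUs whose pooled raw count is below
#' `min_frac` of all assigned reads; (c) drop OTUs whose unique-region
#' coverage is below `min_unique_cov` AND whole-genome coverage below
#' `min_genome_cov` (conjunctive reading; an OTU passing either coverage
#' test is kept). Denominators (per-sample mapped depth, study-total
#' assigned reads) are the pre-filter values frozen at tabulation, so the
#' operation is idempotent. Every removal is logged.
#'
#' @param otu an `"otu_profile"` (normalized or not).
#' @param refdb reference database (unused denominators live in `otu`).
#' @param min_frac minimum pooled relative count (default 1e-6).
#' @param min_unique_cov minimum unique-region coverage (default 1e-4,
#'   i.e. 0.01%).
#' @param min_genome_cov minimum whole-genome coverage (default 1e-2).
#' @param min_sample_depth minimum raw mapped reads per sample
#'   (default 10000).
#' @return filtered profile; removals recorded in `attr(, "filter_log")`
#'   (data.frame entity, type, rule, value, threshold).
#' @export
apply_filters <- function(otu, refdb, min_frac = 1e-6, min_unique_cov = 1e-4,
                          min_genome_cov = 1e-2, min_sample_depth = 10000) {
  log <- list()
  note <- function(entity, type, rule, value, threshold) {
    log[[length(log) + 1L]] <<- data.frame(
      entity = entity, type = type, rule = rule,
      value = value, threshold = threshold, stringsAsFactors = FALSE)
  }

  keep_s <- otu$sample_depth[colnames(otu$counts)] >= min_sample_depth
  for (s in colnames(otu$counts)[!keep_s])
    note(s, "sample", "min_sample_depth", unname(otu$sample_depth[s]),
         min_sample_depth)

  pooled <- rowSums(otu$counts)
  frac <- pooled / otu$total_assigned
  keep_abund <- frac >= min_frac
  for (o in rownames(otu$counts)[!keep_abund])
    note(o, "otu", "min_frac", unname(frac[o]), min_frac)

  cov <- otu$coverage[match(rownames(otu$counts), otu$coverage$genome_id), ]
  drop_cov <- cov$unique_cov < min_unique_cov & cov$genome_cov < min_genome_cov
  for (i in which(keep_abund & drop_cov))
    note(rownames(otu$counts)[i], "otu", "coverage",
         cov$unique_cov[i], min_unique_cov)

  keep_o <- keep_abund & !drop_cov
  out <- otu
  out$counts <- otu$counts[keep_o, keep_s, drop = FALSE]
  if (!is.null(otu$normalized))
    out$normalized <- otu$normalized[keep_o, keep_s, drop = FALSE]
  out$coverage <- otu$coverage[otu$coverage$genome_id %in%
                                 rownames(out$counts), , drop = FALSE]
  out$lineages <- otu$lineages[rownames(out$counts)]
  if (nrow(out$counts) == 0L || ncol(out$counts) == 0L)
    warn("all OTUs or samples removed by filtering")
  attr(out, "filter_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(entity = character(0), type = character(0), rule = character(0),
               value = numeric(0), threshold = numeric(0))
  out
}

#' Convert counts to per-sample relative abundance
#'
#' @param x a numeric matrix (features x samples) or an `"otu_profile"`
#'   (uses the normalized counts when present, raw otherwise).
#' @return matrix whose retained sample columns each sum to 1.
#' @export
to_relative_abundance <- function(x) UseMethod("to_relative_abundance")

#' @export
to_relative_abundance.default <- function(x) {
  x <- as.matrix(x)
  tot <- colSums(x)
  if (any(tot == 0))
    abort("all-zero sample column(s): %s",
          paste(colnames(x)[tot == 0], collapse = ", "))
  sweep(x, 2L, tot, "/")
}

#' @export
to_relative_abundance.otu_profile <- function(x) {
  m <- if (!is.null(x$normalized)) x$normalized else x$counts
  to_relative_abundance.default(m)
}

#' Tabulate per-read LCA lineages into a taxa table
#'
#' Each read is assigned the lowest common ancestor of its full tie set at
#' the given consensus threshold; counts are tabulated by lineage string.
#' Reads with unambiguous hits keep their genome's full lineage, so
#' species-level resolution emerges from the tie structure.
#'
#' @param hits hit table (ties need not be resolved).
#' @param refdb reference database.
#' @param threshold LCA consensus threshold (default 0.8).
#' @return lineage x sample integer matrix.
#' @export
tabulate_lineages <- function(hits, refdb, threshold = 0.8) {
  keys <- unique(hits$tied_genome_ids)
  lca <- vapply(keys, function(k) {
    assign_lineage(strsplit(k, ";", fixed = TRUE)[[1]], refdb, threshold)
  }, character(1))
  lin <- lca[hits$tied_genome_ids]
  feats <- sort(unique(lin))
  samples <- unique(hits$sample_id)
  tab <- table(factor(lin, levels = feats),
               factor(hits$sample_id, levels = samples))
  matrix(as.integer(tab), nrow = length(feats),
         dimnames = list(feats, samples))
}

#' Build KO and enzyme relative-abundance tables from gene hits
#'
#' KO counts are reads hitting genes annotated with that ortholog; enzyme
#' counts collapse KOs to the enzyme level, a KO mapping to k enzymes
#' contributing its full count to each. Both tables are then converted to
#' per-sample relative abundance.
#'
#' @param hits hit table with `gene_id` (NA for intergenic reads).
#' @param refdb reference database.
#' @return list(ko, enzyme, ko_counts, enzyme_counts); `ko`/`enzyme` are
#'   relative-abundance matrices (feature x sample). Empty (0-row) tables
#'   with a warning when no read hits a gene.
#' @export
build_function_tables <- function(hits, refdb) {
  g <- hits[!is.na(hits$gene_id), , drop = FALSE]
  samples <- unique(hits$sample_id)
  if (nrow(g) == 0L) {
    warn("no gene hits; function tables are empty")
    empty <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, samples))
    return(list(ko = empty, enzyme = empty,
                ko_counts = empty, enzyme_counts = empty))
  }
  ko <- refdb$genes$ko_id[match(g$gene_id, refdb$genes$gene_id)]
  if (anyNA(ko))
    abort("gene_id not in reference db: %s",
          paste(unique(g$gene_id[is.na(ko)]), collapse = ", "))
  kos <- sort(unique(ko))
  ko_counts <- table(factor(ko, levels = kos),
                     factor(g$sample_id, levels = samples))
  ko_counts <- matrix(as.integer(ko_counts), nrow = length(kos),
                      dimnames = list(kos, samples))

  map <- refdb$ko2enzyme[refdb$ko2enzyme$ko_id %in% kos, , drop = FALSE]
  enzymes <- sort(unique(map$enzyme_id))
  enzyme_counts <- matrix(0L, nrow = length(enzymes), ncol = length(samples),
                          dimnames = list(enzymes, samples))
  for (i in seq_len(nrow(map))) {
    e <- map$enzyme_id[i]
    enzyme_counts[e, ] <- enzyme_counts[e, ] + ko_counts[map$ko_id[i], ]
  }
  list(ko = to_relative_abundance(ko_counts),
       enzyme = to_relative_abundance(enzyme_counts),
       ko_counts = ko_counts, enzyme_counts = enzyme_counts)
}

#' Collapse ASVs sharing a taxonomic assignment
#'
#' Amplicon features with identical lineage strings are summed into one
#' taxon feature; per-sample totals are conserved.
#'
#' @param asv_table ASV x sample matrix.
#' @param asv_lineages named character vector of lineages, names = ASV ids.
#' @return lineage x sample matrix.
#' @export
collapse_asvs_by_taxonomy <- function(asv_table, asv_lineages) {
  lin <- asv_lineages[rownames(asv_table)]
  if (anyNA(lin) || any(lin == "" | is.na(names(lin))))
    abort("ASV without a taxonomic assignment")
  out <- rowsum(asv_table, group = lin, reorder = TRUE)
  matrix(as.integer(out), nrow = nrow(out), dimnames = dimnames(out))
}

#' Full shotgun profiling pipeline on a hit table
#'
#' Resolve ties, tabulate and normalize OTU counts, apply the depth /
#' abundance / coverage filters, convert to relative abundance, and build
#' the per-read-LCA taxa table and the KO/enzyme function tables.
#'
#' @param hits hit-table data.frame.
#' @param refdb reference database.
#' @param lca_threshold LCA consensus threshold.
#' @param min_frac,min_unique_cov,min_genome_cov,min_sample_depth filter
#'   thresholds, see [apply_filters()].
#' @return list(otu, otu_relabund, taxa_counts, functions, filter_log).
#' @export
profile_hits <- function(hits, refdb, lca_threshold = 0.8, min_frac = 1e-6,
                         min_unique_cov = 1e-4, min_genome_cov = 1e-2,
                         min_sample_depth = 10000) {
  resolved <- resolve_ties_capitalist(hits)
  otu <- tabulate_assignments(resolved, refdb)
  otu <- genome_length_normalize(otu, refdb)
  otu <- apply_filters(otu, refdb, min_frac = min_frac,
                       min_unique_cov = min_unique_cov,
                       min_genome_cov = min_genome_cov,
                       min_sample_depth = min_sample_depth)
  keep <- colnames(otu$counts)
  list(
    otu = otu,
    otu_relabund = to_relative_abundance(otu),
    taxa_counts = tabulate_lineages(
      hits[hits$sample_id %in% keep, , drop = FALSE], refdb, lca_threshold),
    functions = build_function_tables(
      hits[hits$sample_id %in% keep, , drop = FALSE], refdb),
    filter_log = attr(otu, "filter_log")
  )
}
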