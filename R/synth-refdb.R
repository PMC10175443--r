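# Toy reference-genome database emulating a curated whole-genome collection:
# one genome per simulated taxon, fully resolved lineages, unique-region
# intervals, and gene -> KEGG-ortholog -> enzyme annotations.

.PHYLA <- c("Bacteroidota", "Bacillota", "Pseudomonadota", "Actinomycetota")

#' Build the synthetic reference-genome database
#'
#' Taxa are grouped two-per-genus (so genus-level tie sets exist for the LCA
#' path), genera are spread over up to four phyla, and every genome carries a
#' species-level lineage, a genome length drawn from
#' `config$genome_length_range`, a single unique-region interval covering
#' `config$unique_fraction` of the genome, and `config$n_kos_per_genome`
#' gene records annotated with KEGG orthologs; orthologs map onto a smaller
#' enzyme set, some to two enzymes.
#'
#' @param config a [simulation_config()].
#' @param seed optional seed; defaults to `config$seed + 2`.
#' @return list of class `"reference_db"` with data.frames `genomes`
#'   (genome_id, taxon_id, lineage, length, unique_intervals), `genes`
#'   (genome_id, gene_id, start, end, ko_id) and `ko2enzyme`
#'   (ko_id, enzyme_id). Intervals are half-open, 0-based, bp.
#' @export
build_reference_db <- function(config, seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$seed + 2L
  nt <- config$n_taxa
  taxa <- sprintf("T%03d", seq_len(nt))
  genome_id <- sprintf("G%03d", seq_len(nt))
  genus_idx <- (seq_len(nt) + 1L) %/% 2L
  within <- seq_len(nt) - 2L * (genus_idx - 1L)
  phylum <- .PHYLA[(genus_idx - 1L) %% length(.PHYLA) + 1L]
  lineage <- vapply(seq_len(nt), function(i) {
    lineage_make(c("Bacteria", phylum[i],
                   paste0(sub("ota$", "ia", phylum[i])),
                   sprintf("Order%02d", genus_idx[i]),
                   sprintf("Family%02d", genus_idx[i]),
                   sprintf("Genus%02d", genus_idx[i]),
                   sprintf("Genus%02d species%d", genus_idx[i], within[i])))
  }, character(1))

  with_seed(seed, {
    len <- config$genome_length_range[1] +
      floor(stats::runif(nt) * (diff(config$genome_length_range) + 1L))
    len <- as.integer(pmin(len, config$genome_length_range[2]))
    ulen <- pmax(1L, as.integer(round(config$unique_fraction * len)))
    ustart <- vapply(seq_len(nt), function(i) {
      sample.int(len[i] - ulen[i] + 1L, 1L) - 1L
    }, integer(1))

    nko <- config$n_kos_per_genome
    ko_pool <- sprintf("K%05d", seq_len(max(2L, 2L * nko)))
    gene_rows <- lapply(seq_len(nt), function(i) {
      slot <- len[i] %/% nko
      glen <- max(1L, min(900L, slot))
      start <- vapply(seq_len(nko), function(k) {
        (k - 1L) * slot + sample.int(max(1L, slot - glen + 1L), 1L) - 1L
      }, integer(1))
      data.frame(
        genome_id = genome_id[i],
        gene_id = sprintf("%s_g%02d", genome_id[i], seq_len(nko)),
        start = start, end = start + glen,
        ko_id = sample(ko_pool, nko),
        stringsAsFactors = FALSE
      )
    })
    genes <- do.call(rbind, gene_rows)

    n_enz <- max(1L, length(ko_pool) %/% 2L)
    enzymes <- sprintf("EC:1.1.1.%d", seq_len(n_enz))
    k <- seq_along(ko_pool)
    ko2enzyme <- data.frame(ko_id = ko_pool,
                            enzyme_id = enzymes[(k - 1L) %% n_enz + 1L],
                            stringsAsFactors = FALSE)
    multi <- which(k %% 4L == 0L & n_enz > 1L)
    if (length(multi) > 0L) {
      ko2enzyme <- rbind(ko2enzyme, data.frame(
        ko_id = ko_pool[multi],
        enzyme_id = enzymes[multi %% n_enz + 1L],
        stringsAsFactors = FALSE
      ))
      ko2enzyme <- ko2enzyme[!duplicated(ko2enzyme), ]
      ko2enzyme <- ko2enzyme[order(ko2enzyme$ko_id, ko2enzyme$enzyme_id), ]
      rownames(ko2enzyme) <- NULL
    }

    genomes <- data.frame(
      genome_id = genome_id, taxon_id = taxa, lineage = lineage,
      length = len,
      unique_intervals = sprintf("%d-%d", ustart, ustart + ulen),
      stringsAsFactors = FALSE
    )
    structure(list(genomes = genomes, genes = genes, ko2enzyme = ko2enzyme),
              class = "reference_db")
  })
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d genomes, %d gene records, %d KO->enzyme links\n",
              nrow(x$genomes), nrow(x$genes), nrow(x$ko2enzyme)))
  invisible(x)
}

# "s-e;s-e" -> 2-column matrix of half-open intervals
parse_intervals <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
  colnames(m) <- c("start", "end")
  m
}
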