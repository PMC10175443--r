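.READ_LEN <- 100L

#' Generate a read-level hit table for the shotgun path
#'
#' Emulates the post-alignment output of an all-vs-all aligner: each read
#' from taxon t aligns to t's genome at a uniform random start; with
#' probability `config$p_tie` (and when t's genus holds more than one
#' genome) the read is reported with a tie set spanning all genomes of that
#' genus, which exercises downstream lowest-common-ancestor assignment.
#' Reads are 100 bp, error-free; reads overlapping an annotated gene carry
#' its gene_id.
#'
#' @param counts taxa x samples integer matrix (shotgun samples), rownames =
#'   taxon ids matching `refdb$genomes$taxon_id`.
#' @param refdb a [build_reference_db()] object.
#' @param config a [simulation_config()] (uses `p_tie`).
#' @param seed optional seed; defaults to `config$seed + 3`.
#' @return data.frame(sample_id, read_id, tied_genome_ids, position, gene_id)
#'   with one row per read; `tied_genome_ids` is semicolon-joined,
#'   `gene_id` is NA for intergenic reads.
#' @export
generate_hit_table <- function(counts, refdb, config, seed = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(names(counts), "sample1"))
  if (is.null(rownames(counts))) abort("counts must carry taxon rownames")
  gmap <- match(rownames(counts), refdb$genomes$taxon_id)
  if (anyNA(gmap))
    abort("taxon without genome mapping: %s",
          paste(rownames(counts)[is.na(gmap)], collapse = ", "))
  if (is.null(seed)) seed <- config$seed + 3L

  glen <- refdb$genomes$length
  gid <- refdb$genomes$genome_id
  genus <- lineage_rank_value(refdb$genomes$lineage, "genus")
  genus_members <- split(gid, genus)
  tie_of <- vapply(seq_along(gid), function(i) {
    mem <- sort(genus_members[[genus[i]]])
    paste(mem, collapse = ";")
  }, character(1))
  tie_minlen <- vapply(seq_along(gid), function(i) {
    mem <- genus_members[[genus[i]]]
    min(glen[match(mem, gid)])
  }, numeric(1))

  genes_by_genome <- split(refdb$genes, refdb$genes$genome_id)
  gene_lookup <- function(genome_i, pos) {
    g <- genes_by_genome[[gid[genome_i]]]
    if (is.null(g) || nrow(g) == 0L) return(rep(NA_character_, length(pos)))
    g <- g[order(g$start), , drop = FALSE]
    idx <- findInterval(pos + .READ_LEN - 1L, g$start)
    hit <- idx >= 1L & ifelse(idx >= 1L, g$end[pmax(idx, 1L)] > pos, FALSE)
    out <- rep(NA_character_, length(pos))
    out[hit] <- g$gene_id[idx[hit]]
    out
  }

  with_seed(seed, {
    chunks <- vector("list", ncol(counts) * nrow(counts))
    ci <- 0L
    for (s in seq_len(ncol(counts))) {
      sample_id <- colnames(counts)[s]
      offset <- 0L
      for (t in seq_len(nrow(counts))) {
        n <- counts[t, s]
        if (n == 0L) next
        gi <- gmap[t]
        tied <- stats::runif(n) < config$p_tie & grepl(";", tie_of[gi], fixed = TRUE)
        maxstart <- ifelse(tied, tie_minlen[gi], glen[gi]) - .READ_LEN
        if (any(maxstart < 0)) abort("genome shorter than read length")
        pos <- as.integer(floor(stats::runif(n) * (maxstart + 1L)))
        ci <- ci + 1L
        chunks[[ci]] <- data.frame(
          sample_id = sample_id,
          read_id = sprintf("%s_r%06d", sample_id, offset + seq_len(n)),
          tied_genome_ids = ifelse(tied, tie_of[gi], gid[gi]),
          position = pos,
          gene_id = gene_lookup(gi, pos),
          stringsAsFactors = FALSE
        )
        offset <- offset + n
      }
    }
    hits <- do.call(rbind, chunks[seq_len(ci)])
    if (is.null(hits))
      hits <- data.frame(sample_id = character(0), read_id = character(0),
                         tied_genome_ids = character(0), position = integer(0),
                         gene_id = character(0), stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    hits
  })
}

#' Simulate an amplicon ASV table with pre-assigned lineages
#'
#' Emits denoised amplicon features directly (denoising itself is out of
#' scope): each taxon yields one or two ASVs sharing a lineage truncated at
#' genus, except a `p_species_16s` fraction of taxa which stay resolved to
#' species — mirroring the limited taxonomic resolution of short-amplicon
#' features. Counts of a taxon are split across its ASVs binomially.
#'
#' @param counts taxa x samples integer matrix of amplicon counts.
#' @param refdb reference database supplying the full lineages.
#' @param config a [simulation_config()] (`p_species_16s`).
#' @param seed optional seed; defaults to `config$seed + 4`.
#' @return list(table = ASV x samples integer matrix,
#'   lineages = named character of ASV lineage strings).
#' @export
simulate_asv_table <- function(counts, refdb, config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 4L
  tmap <- match(rownames(counts), refdb$genomes$taxon_id)
  if (anyNA(tmap)) abort("taxon without genome mapping in ASV simulation")
  full <- refdb$genomes$lineage[tmap]
  with_seed(seed, {
    species_res <- stats::runif(nrow(counts)) < config$p_species_16s
    depth <- ifelse(species_res, 7L, 6L)
    n_asv <- 1L + stats::rbinom(nrow(counts), 1L, 0.3)
    rows <- list(); lin <- character(0); ids <- character(0)
    k <- 0L
    for (t in seq_len(nrow(counts))) {
      lt <- lineage_truncate(full[t], depth[t])
      if (n_asv[t] == 1L) {
        k <- k + 1L
        rows[[k]] <- counts[t, ]; lin[k] <- lt
        ids[k] <- sprintf("ASV%04d", k)
      } else {
        a <- stats::rbinom(ncol(counts), counts[t, ], 0.5)
        k <- k + 1L
        rows[[k]] <- a; lin[k] <- lt; ids[k] <- sprintf("ASV%04d", k)
        k <- k + 1L
        rows[[k]] <- counts[t, ] - a; lin[k] <- lt; ids[k] <- sprintf("ASV%04d", k)
      }
    }
    tab <- do.call(rbind, rows)
    storage.mode(tab) <- "integer"
    dimnames(tab) <- list(ids, colnames(counts))
    list(table = tab, lineages = stats::setNames(lin, ids))
  })
}
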