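# Tab-delimited readers/writers with strict schema validation. All files are
# UTF-8 TSV with a header row; feature tables put the feature id in the
# first column with sample ids as the remaining columns.

read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L)
      abort("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a feature table
#'
#' Layout: first column is the feature id, remaining columns are samples.
#'
#' @param path TSV path.
#' @return numeric matrix, features x samples.
#' @export
read_feature_table <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) abort("%s: feature table needs id + sample columns", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    abort("%s: duplicate feature id(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    abort("%s: non-numeric cells in column(s): %s", path,
          paste(names(df[-1])[bad], collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' @rdname read_feature_table
#' @param x feature x sample matrix.
#' @param id_column header for the feature-id column.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(x))
  write_tsv(df, path)
}

#' Read / write the sample metadata table
#'
#' @param path TSV path.
#' @return data.frame with the design columns.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(path, required = c("sample_id", "subject", "day",
                                            "week", "extraction_rep",
                                            "libprep_rep", "modality"))
  if (anyDuplicated(df$sample_id))
    abort("%s: duplicate sample_id(s)", path)
  bad <- !df$modality %in% c("AMPLICON", "SHOTGUN")
  if (any(bad))
    abort("%s: invalid modality at line %d", path, which(bad)[1] + 1L)
  df
}

#' @rdname read_metadata
#' @param metadata design data.frame.
#' @export
write_metadata <- function(metadata, path) write_tsv(metadata, path)

#' Read / write a square distance matrix
#'
#' Layout: header row of sample ids, first column of sample ids, full
#' square matrix. Asymmetries beyond 1e-8 are rejected with the offending
#' row/column named.
#'
#' @param path TSV path.
#' @return symmetric numeric matrix with sample-id dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv_checked(path)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    abort("%s: matrix must be square with matching row/column ids", path)
  asym <- abs(m - t(m))
  if (max(asym) > 1e-8) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    abort("%s: asymmetric at (%s, %s): |d_ij - d_ji| = %.3g", path,
          rownames(m)[w[1]], colnames(m)[w[2]], max(asym))
  }
  m
}

#' @rdname read_distance_matrix
#' @param D symmetric matrix.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  names(df) <- c("sample_id", colnames(D))
  write_tsv(df, path)
}

#' Read / write a read-level hit table
#'
#' @param path TSV path.
#' @param refdb optional reference database; when given, every tied genome
#'   id is checked against it.
#' @return data.frame(sample_id, read_id, tied_genome_ids, position, gene_id).
#' @export
read_hit_table <- function(path, refdb = NULL) {
  df <- read_tsv_checked(path, required = c("sample_id", "read_id",
                                            "tied_genome_ids", "position",
                                            "gene_id"))
  df$gene_id[df$gene_id == "-"] <- NA_character_
  if (!is.null(refdb)) {
    gids <- unique(unlist(split_ties(unique(df$tied_genome_ids))))
    unknown <- setdiff(gids, refdb$genomes$genome_id)
    if (length(unknown) > 0L)
      abort("%s: unknown genome id(s): %s", path,
            paste(unknown, collapse = ", "))
  }
  df
}

#' @rdname read_hit_table
#' @param hits hit-table data.frame.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[, c("sample_id", "read_id", "tied_genome_ids", "position",
                  "gene_id")]
  out$gene_id[is.na(out$gene_id)] <- "-"
  write_tsv(out, path)
}

#' Read / write the reference database directory
#'
#' Three TSVs: `genomes.tsv` (genome_id, taxon_id, lineage, length,
#' unique_intervals), `genes.tsv` (genome_id, gene_id, start, end, ko_id)
#' and `ko2enzyme.tsv` (ko_id, enzyme_id).
#'
#' @param dir directory path.
#' @return a `"reference_db"`.
#' @export
read_reference_db <- function(dir) {
  genomes <- read_tsv_checked(file.path(dir, "genomes.tsv"),
                              required = c("genome_id", "taxon_id", "lineage",
                                           "length", "unique_intervals"))
  if (anyDuplicated(genomes$genome_id))
    abort("duplicate genome ids in %s", dir)
  genes <- read_tsv_checked(file.path(dir, "genes.tsv"),
                            required = c("genome_id", "gene_id", "start",
                                         "end", "ko_id"))
  ko2enzyme <- read_tsv_checked(file.path(dir, "ko2enzyme.tsv"),
                                required = c("ko_id", "enzyme_id"))
  structure(list(genomes = genomes, genes = genes, ko2enzyme = ko2enzyme),
            class = "reference_db")
}

#' @rdname read_reference_db
#' @param refdb a `"reference_db"`.
#' @export
write_reference_db <- function(refdb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(refdb$genomes, file.path(dir, "genomes.tsv"))
  write_tsv(refdb$genes, file.path(dir, "genes.tsv"))
  write_tsv(refdb$ko2enzyme, file.path(dir, "ko2enzyme.tsv"))
  invisible(dir)
}

#' Write variation records
#'
#' @param records output of [partition_dissimilarities()].
#' @param path TSV path.
#' @export
write_variation_records <- function(records, path) write_tsv(records, path)

#' @rdname write_variation_records
#' @export
read_variation_records <- function(path) {
  read_tsv_checked(path, required = c("sample_a", "sample_b", "modality",
                                      "category", "dissimilarity"))
}
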