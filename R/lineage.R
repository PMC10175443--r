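# Ranked taxonomy strings of the form
#   k__Bacteria;p__Bacteroidota;...;s__Bacteroides uniformis
# Deeper ranks may be absent, but a present rank implies all shallower ranks
# are present (no gaps).

.RANKS <- c("kingdom", "phylum", "class", "order", "family",
            "genus", "species", "strain")
.RANK_PREFIX <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__", "t__")

#' Taxonomic ranks used throughout the package
#'
#' @return character vector of the eight ranks from kingdom to strain.
#' @export
lineage_ranks <- function() .RANKS

#' Split a lineage string into rank values
#'
#' @param lineage a single lineage string, e.g. `"k__Bacteria;g__Bacteroides"`.
#' @return named character vector (names are ranks) of the present levels.
#' @export
lineage_parse <- function(lineage) {
  if (length(lineage) != 1L || is.na(lineage) || !is.character(lineage))
    abort("lineage must be a single non-NA string")
  if (lineage == "") return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  pref <- substr(parts, 1L, 3L)
  idx <- match(pref, .RANK_PREFIX)
  if (anyNA(idx))
    abort("malformed lineage string: unknown rank prefix in '%s'", lineage)
  if (is.unsorted(idx, strictly = TRUE) || !identical(idx, seq_along(idx)))
    abort("malformed lineage string (rank gap or disorder): '%s'", lineage)
  stats::setNames(substring(parts, 4L), .RANKS[idx])
}

#' Number of resolved ranks in a lineage
#'
#' @param lineage character vector of lineage strings.
#' @return integer vector of depths (0 = unassigned, 8 = strain).
#' @export
lineage_depth <- function(lineage) {
  vapply(lineage, function(l) {
    if (is.na(l) || l == "") return(0L)
    length(strsplit(l, ";", fixed = TRUE)[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Truncate lineages to a maximum depth
#'
#' @param lineage character vector of lineage strings.
#' @param depth integer number of ranks to keep (1 = kingdom only).
#' @return character vector of truncated lineage strings.
#' @export
lineage_truncate <- function(lineage, depth) {
  vapply(lineage, function(l) {
    parts <- strsplit(l, ";", fixed = TRUE)[[1]]
    paste(utils::head(parts, depth), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract one rank's value from lineage strings
#'
#' @param lineage character vector of lineage strings.
#' @param rank one of [lineage_ranks()].
#' @return character vector; `NA` where the rank is absent.
#' @export
lineage_rank_value <- function(lineage, rank) {
  rank <- match.arg(rank, .RANKS)
  i <- match(rank, .RANKS)
  pref <- .RANK_PREFIX[i]
  vapply(lineage, function(l) {
    if (is.na(l) || l == "") return(NA_character_)
    parts <- strsplit(l, ";", fixed = TRUE)[[1]]
    hit <- parts[startsWith(parts, pref)]
    if (length(hit) == 0L) NA_character_ else substring(hit[1], 4L)
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble a lineage string from rank values
#'
#' @param values character vector of rank values ordered kingdom-first; may be
#'   shorter than eight entries.
#' @return lineage string.
#' @export
lineage_make <- function(values) {
  if (length(values) == 0L) return("")
  if (length(values) > length(.RANKS)) abort("at most 8 ranks supported")
  paste0(.RANK_PREFIX[seq_along(values)], values, collapse = ";")
}

#' Compare two lineages for exact or nested agreement
#'
#' Two lineages match exactly when their strings are identical; they are
#' nested when one is a strict rank-prefix of the other (e.g. a species-level
#' assignment falling within a known genus-level assignment).
#'
#' @param a,b lineage strings.
#' @return `"exact"`, `"nested"`, or `"none"`.
#' @export
match_lineages <- function(a, b) {
  pa <- lineage_parse(a)
  pb <- lineage_parse(b)
  if (identical(a, b)) return("exact")
  na <- length(pa); nb <- length(pb)
  k <- min(na, nb)
  if (k > 0L && na != nb && identical(unname(pa[seq_len(k)]), unname(pb[seq_len(k)])))
    return("nested")
  "none"
}
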