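# Rarefaction and alpha/beta diversity. Standard metrics delegate to vegan;
# PCoA is computed directly from the Gower-centered matrix because the
# dispersion test downstream needs the full eigensystem including negative
# axes.

#' Rarefy a count table to an even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`
#' (default: the smallest sample total, the convention for comparing
#' diversity across samples of unequal depth).
#'
#' @param x feature x sample matrix of nonnegative integer counts.
#' @param depth target depth; must not exceed any sample's total.
#' @param seed optional seed for reproducible subsampling.
#' @return integer matrix with every column summing to `depth`.
#' @export
rarefy_table <- function(x, depth = NULL, seed = NULL) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != floor(x))) abort("counts must be nonnegative integers")
  tot <- colSums(x)
  if (is.null(depth)) depth <- min(tot)
  if (!is_count_scalar(depth) || depth <= 0) abort("depth must be a positive integer")
  if (any(tot < depth))
    abort("depth %d exceeds total of sample(s): %s", depth,
          paste(colnames(x)[tot < depth], collapse = ", "))
  # rrarefy's "observed counts" heads-up is redundant here: integer counts
  # are enforced above
  out <- with_seed(seed, t(suppressWarnings(vegan::rrarefy(t(x), sample = depth))))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(x)
  out
}

#' Alpha diversity of a count or abundance vector
#'
#' Shannon index uses natural log by default (`H = -sum p_i log p_i`);
#' Chao1 is the bias-corrected estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (singletons/doubletons require
#' integer counts); observed is the number of nonzero features.
#'
#' @param x nonnegative numeric vector (a single sample), not all zero.
#' @param metric one of `"shannon"`, `"chao1"`, `"observed"`.
#' @param base log base for Shannon (default `exp(1)`; use 2 for bits).
#' @return a single number.
#' @export
alpha_diversity <- function(x, metric = c("shannon", "chao1", "observed"),
                            base = exp(1)) {
  metric <- match.arg(metric)
  x <- as.numeric(x)
  if (any(x < 0)) abort("negative abundance")
  if (sum(x) == 0) abort("all-zero vector")
  switch(metric,
    shannon = as.numeric(vegan::diversity(x, index = "shannon", base = base)),
    chao1 = {
      if (any(x != floor(x))) abort("chao1 requires integer counts")
      s <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    },
    observed = sum(x > 0)
  )
}

#' Alpha diversity for every sample of a table
#'
#' @param x feature x sample matrix.
#' @param metrics metrics to compute (default all three).
#' @inheritParams alpha_diversity
#' @return data.frame with sample_id and one column per metric.
#' @export
alpha_diversity_table <- function(x, metrics = c("shannon", "chao1", "observed"),
                                  base = exp(1)) {
  out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
  for (m in metrics)
    out[[m]] <- apply(x, 2L, alpha_diversity, metric = m, base = base)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between sample columns.
#'
#' @param x feature x sample matrix of nonnegative abundances.
#' @return symmetric sample x sample matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("negative abundances")
  zero <- colSums(x) == 0
  if (sum(zero) >= 2L)
    abort("Bray-Curtis undefined between all-zero samples: %s",
          paste(colnames(x)[zero], collapse = ", "))
  D <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  dimnames(D) <- list(colnames(x), colnames(x))
  D
}

#' Principal coordinates analysis
#'
#' Gower-centers `-D^2 / 2` and eigendecomposes. Coordinates are returned
#' for positive-eigenvalue axes only; axis `i` explains
#' `lambda_i / sum(lambda_+)` of the (positive) variation. Negative
#' eigenvalues (non-Euclidean input) are reported but carry no coordinates;
#' no Cailliez/Lingoes correction is applied.
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param n_axes maximum number of axes to keep (default: all positive).
#' @return list of class `"pcoa_result"`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (per kept axis).
#' @export
pcoa <- function(D, n_axes = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    abort("distance matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  e <- eigen(G, symmetric = TRUE)
  lambda <- e$values
  tol <- max(abs(lambda)) * 1e-9
  pos <- which(lambda > tol)
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 0)
    prop <- numeric(0)
  } else {
    if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
    coords <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(lambda[pos]), length(pos))
    prop <- lambda[pos] / sum(lambda[lambda > tol])
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- if (ncol(coords)) paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = lambda,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(2L, length(x$proportion_explained))
  cat(sprintf("pcoa_result: %d samples, %d positive axes",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (k > 0)
    cat(sprintf("; PC1..PC%d explain %s", k,
                paste(sprintf("%.1f%%", 100 * x$proportion_explained[seq_len(k)]),
                      collapse = ", ")))
  cat("\n")
  invisible(x)
}
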