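# The statistical battery, implemented from first principles: PERMANOVA,
# homogeneity of multivariate dispersions, Kruskal-Wallis with Dunn's
# post-hoc and Benjamini-Hochberg adjustment, additive two-way ANOVA, and
# pooled-variance t-tests. Null distributions for the permutation tests come
# from label permutation; only chi-square/F/normal/t tail probabilities are
# taken from base R.

stat_result <- function(method, statistic, df, p_value, r_squared = NA_real_,
                        p_adjusted = NA_real_, n_perm = NA_integer_,
                        comparison = NA_character_, extra = NULL) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   r_squared = r_squared, p_value = p_value,
                   p_adjusted = p_adjusted, n_perm = n_perm,
                   comparison = comparison), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.na(x$r_squared)) cat(sprintf(", R2 = %.4f", x$r_squared))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p.adj = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (exhaustive tests, n <= 9)
all_permutations <- function(n) {
  if (n > 9L) abort("exhaustive permutations limited to n <= 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

permanova_f <- function(D2, groups) {
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L)
      ss_within <- ss_within +
        sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  a <- length(unique(groups))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_between / ss_total, ss_total = ss_total)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sum of squared dissimilarities into between- and
#' within-group components: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, pseudo-F =
#' `(SS_between/(a-1)) / (SS_within/(n-a))`, `R^2 = SS_between/SS_total`.
#' The p-value comes from permuting group labels:
#' `(count{F_perm >= F_obs} + 1) / (n_perm + 1)` for the sampled null, or
#' the exact fraction over all `n!` label arrangements when
#' `n_perm = "all"`. On one-dimensional Euclidean distances the pseudo-F
#' equals the classical one-way ANOVA F.
#'
#' @param D distance matrix (matrix or `dist`).
#' @param groups group labels, one per sample.
#' @param n_perm number of permutations (default 999), or `"all"` for
#'   exhaustive enumeration (n <= 9).
#' @param seed optional seed for the permutation sampler.
#' @return a `"stat_result"` with statistic (pseudo-F), df = (a-1, n-a),
#'   `r_squared` and the permutation p-value.
#' @export
permanova <- function(D, groups, n_perm = 999L, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(groups) != n) abort("groups length must match distance matrix size")
  groups <- as.character(groups)
  a <- length(unique(groups))
  if (a < 2L) abort("need at least 2 groups")
  D2 <- D^2
  obs <- permanova_f(D2, groups)
  df <- c(a - 1L, n - a)
  if (obs[["ss_total"]] <= .Machine$double.eps) {
    warn("total sum of squares is zero; pseudo-F undefined")
    return(stat_result("permanova", NaN, df, NA_real_, r_squared = 0,
                       n_perm = 0L))
  }
  eps <- 1e-8 * max(obs[["f"]], 1)
  if (identical(n_perm, "all") || is.infinite(n_perm)) {
    P <- all_permutations(n)
    fs <- apply(P, 1L, function(p) permanova_f(D2, groups[p])[["f"]])
    p_val <- mean(fs >= obs[["f"]] - eps)
    n_used <- nrow(P)
  } else {
    fs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      permanova_f(D2, groups[sample.int(n)])[["f"]], numeric(1)))
    p_val <- (sum(fs >= obs[["f"]] - eps) + 1) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  stat_result("permanova", unname(obs[["f"]]), df, p_val,
              r_squared = unname(obs[["r2"]]), n_perm = n_used)
}

dispersion_distances <- function(pos, neg, groups, warn_negative = FALSE) {
  z2 <- numeric(nrow(pos))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(pos[idx, , drop = FALSE])
    cn <- colMeans(neg[idx, , drop = FALSE])
    dp <- sweep(pos[idx, , drop = FALSE], 2L, cp)
    dn <- sweep(neg[idx, , drop = FALSE], 2L, cn)
    z2[idx] <- rowSums(dp^2) - rowSums(dn^2)
  }
  if (any(z2 < 0)) {
    if (warn_negative)
      warn("%d negative squared dispersion distance(s) truncated to zero",
           sum(z2 < 0))
    z2[z2 < 0] <- 0
  }
  sqrt(z2)
}

anova_f_1way <- function(y, groups) {
  grand <- mean(y)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    yi <- y[groups == g]
    ssb <- ssb + length(yi) * (mean(yi) - grand)^2
    ssw <- ssw + sum((yi - mean(yi))^2)
  }
  a <- length(unique(groups)); n <- length(y)
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates (keeping negative
#' axes separately), computes each sample's distance to its group centroid
#' as `sqrt(d+^2 - d-^2)` (squared distance on positive-eigenvalue axes
#' minus squared distance on negative ones; negative results truncated to 0
#' with a warning), and tests dispersion equality with a one-way ANOVA F on
#' those distances. The p-value permutes group labels, recomputing centroids
#' and distances for each permutation.
#'
#' @inheritParams permanova
#' @return a `"stat_result"` (F, df, permutation p) with the per-sample
#'   observed dispersion distances in `$distances`.
#' @export
betadisper_test <- function(D, groups, n_perm = 999L, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(groups) != n) abort("groups length must match distance matrix size")
  groups <- as.character(groups)
  a <- length(unique(groups))
  if (a < 2L) abort("need at least 2 groups")
  if (any(table(groups) == 1L))
    warn("group(s) of size 1: dispersion distance is 0 by construction")
  # full eigensystem: pcoa() keeps only positive axes' coordinates, the
  # dispersion correction needs the negative ones too
  A <- -0.5 * D^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values), .Machine$double.eps) * 1e-9
  posax <- e$values > tol
  negax <- e$values < -tol
  pos <- e$vectors[, posax, drop = FALSE] %*%
    diag(sqrt(e$values[posax]), sum(posax))
  neg <- e$vectors[, negax, drop = FALSE] %*%
    diag(sqrt(-e$values[negax]), sum(negax))

  z <- dispersion_distances(pos, neg, groups, warn_negative = TRUE)
  f_obs <- anova_f_1way(z, groups)
  df <- c(a - 1L, n - a)
  if (!is.finite(f_obs)) {
    warn("zero within-group dispersion variance; F undefined")
    return(stat_result("betadisper", NaN, df, NA_real_, n_perm = 0L,
                       extra = list(distances = stats::setNames(z, rownames(D)))))
  }
  eps <- 1e-8 * max(abs(f_obs), 1)
  fs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    gp <- groups[sample.int(n)]
    anova_f_1way(dispersion_distances(pos, neg, gp), gp)
  }, numeric(1)))
  p_val <- (sum(fs[is.finite(fs)] >= f_obs - eps) + 1) / (n_perm + 1)
  stat_result("betadisper", f_obs, df, p_val, n_perm = as.integer(n_perm),
              extra = list(distances = stats::setNames(z, rownames(D))))
}

tie_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test
#'
#' `H = 12/(N(N+1)) sum n_g (Rbar_g - (N+1)/2)^2`, divided by the tie
#' correction `1 - sum(t^3 - t)/(N^3 - N)`; p from the chi-square
#' distribution with a-1 df.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return a `"stat_result"` (H, df, p).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (any(table(groups) == 0L) || length(unique(groups)) < 2L)
    abort("need at least 2 non-empty groups")
  n <- length(values)
  if (n < 3L) abort("need N >= 3 observations")
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(unique(groups), function(g) {
      rg <- r[groups == g]
      length(rg) * (mean(rg) - (n + 1) / 2)^2
    }, numeric(1)))
  corr <- 1 - tie_sum(r) / (n^3 - n)
  a <- length(unique(groups))
  if (corr <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h / corr
    p <- stats::pchisq(h, df = a - 1, lower.tail = FALSE)
  }
  stat_result("kruskal_wallis", h, a - 1L, p)
}

#' Dunn's post-hoc test for all group pairs
#'
#' On the joint ranking,
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_a + 1/n_b))`
#' with tie term `T = sum(t^3 - t)`; two-sided normal p-values,
#' Benjamini-Hochberg adjusted across the family of pairs.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param adjust `"BH"` (default) or `"none"`.
#' @return data.frame(comparison, z, p_value, p_adjusted), one row per
#'   unordered group pair.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) abort("need at least 2 groups")
  n <- length(values)
  r <- rank(values)
  sigma2 <- n * (n + 1) / 12 - tie_sum(r) / (12 * (n - 1))
  pairs <- utils::combn(lev, 2L)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    ra <- r[groups == pairs[1, k]]
    rb <- r[groups == pairs[2, k]]
    se <- sqrt(sigma2 * (1 / length(ra) + 1 / length(rb)))
    if (se == 0) return(0)
    (mean(ra) - mean(rb)) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
    z = z, p_value = p,
    p_adjusted = if (adjust == "BH") bh_adjust(p) else p,
    stringsAsFactors = FALSE
  )
}

#' Additive two-way ANOVA (Type II sums of squares)
#'
#' Fits `y ~ A + B` without interaction; each factor's sum of squares is
#' the drop in residual SS from adding it to the model containing the other
#' (Type II, identical to Type I on balanced data). Residual df is
#' `N - a - b + 1`.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (>= 2 levels each, all cells non-empty).
#' @return list of two `"stat_result"`s named `factor_a` and `factor_b`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    abort("both factors need >= 2 levels")
  if (any(table(fa, fb) == 0L)) abort("empty cell in the two-way layout")
  y <- as.numeric(values)
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  X_full <- stats::model.matrix(~ fa + fb)
  X_a <- stats::model.matrix(~ fa)
  X_b <- stats::model.matrix(~ fb)
  rss_full <- rss(X_full)
  ss_a <- rss(X_b) - rss_full
  ss_b <- rss(X_a) - rss_full
  df_a <- nlevels(fa) - 1L
  df_b <- nlevels(fb) - 1L
  df_res <- length(y) - nlevels(fa) - nlevels(fb) + 1L
  ms_res <- rss_full / df_res
  f_a <- (ss_a / df_a) / ms_res
  f_b <- (ss_b / df_b) / ms_res
  list(
    factor_a = stat_result("two_way_anova", f_a, c(df_a, df_res),
                           stats::pf(f_a, df_a, df_res, lower.tail = FALSE),
                           comparison = "factor_a"),
    factor_b = stat_result("two_way_anova", f_b, c(df_b, df_res),
                           stats::pf(f_b, df_b, df_res, lower.tail = FALSE),
                           comparison = "factor_b")
  )
}

#' Two-sample pooled-variance (Student's) t-test
#'
#' @param values_a,values_b numeric samples (each n >= 2).
#' @param equal_var must be TRUE (pooled variance); the Welch variant is not
#'   provided.
#' @return a `"stat_result"` (t, df = n_a + n_b - 2, two-sided p).
#' @export
t_test <- function(values_a, values_b, equal_var = TRUE) {
  stopifnot(isTRUE(equal_var))
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) abort("each sample needs n >= 2")
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  df <- na + nb - 2L
  if (sp2 == 0) {
    warn("zero pooled variance; t undefined")
    return(stat_result("t_test", NaN, df, NA_real_))
  }
  t <- (mean(values_a) - mean(values_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  stat_result("t_test", t, df, 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorted ascending, `adj_i = min_{j >= i} p_j m / j`, capped at 1, with the
#' original order restored.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m <= 1L) return(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
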