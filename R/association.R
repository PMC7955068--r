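#' Spearman association of every HIF with a molecular signature
#'
#' Spearman rank correlation (mid-ranks for ties) of each feature column
#' against a per-patient signature vector, with the two-sided p-value from
#' the t approximation on `n - 2` degrees of freedom. Constant columns give
#' `NA`.
#'
#' @param hm a `hif_matrix` (patient level).
#' @param signature numeric vector aligned to the matrix rows (or named by
#'   patient id).
#' @return data frame with `feature_id`, `rho`, `p`.
#' @export
spearman_assoc <- function(hm, signature) {
  x <- hm$values
  if (!is.null(names(signature)))
    signature <- signature[rownames(x)]
  ok <- !is.na(signature)
  x <- x[ok, , drop = FALSE]
  signature <- signature[ok]
  n <- length(signature)
  if (n < 5) stop("need at least 5 paired observations")
  rs <- rank(signature)
  rho <- suppressWarnings(as.vector(stats::cor(apply(x, 2, rank), rs)))
  constant <- apply(x, 2, function(col) length(unique(col)) < 2)
  rho[constant] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  data.frame(feature_id = colnames(x), rho = rho, p = p,
             stringsAsFactors = FALSE)
}

#' Empirical Brown's method for combining dependent p-values
#'
#' Extends Fisher's method to dependent tests: each underlying variable is
#' transformed to `w_i(s) = -2 * log(1 - F_i(x_is))` with `F_i` the
#' within-variable empirical CDF using the `(rank - 0.5)/n` convention (a
#' continuity correction that avoids `log(0)`); the empirical covariances of
#' `w` across samples inflate the variance of the Fisher statistic
#' `Psi = -2 * sum(log p_i)`, which is then referred to a scaled chi-square:
#' `E = 2k`, `Var = 4k + 2*sum_{i<j} cov_ij`, `f = 2 E^2 / Var`,
#' `c = Var / (2E)`, `p = P(chisq_f > Psi / c)`. With all covariances zero
#' this reduces exactly to Fisher's method. Input p-values are floored at
#' `1e-30` (machine-precision floor).
#'
#' @param data k x n matrix: the k underlying variables (rows) over n
#'   samples, used only to estimate the dependence.
#' @param pvals the k p-values to combine.
#' @param pvalue_floor lower clamp for the input p-values.
#' @return list with `p_combined`, `psi`, `scale_c`, `df_f`.
#' @export
empirical_browns <- function(data, pvals, pvalue_floor = 1e-30) {
  data <- as.matrix(data)
  k <- nrow(data)
  n <- ncol(data)
  stopifnot(k == length(pvals), k >= 1)
  pvals <- pmin(pmax(pvals, pvalue_floor), 1)
  if (k == 1) {
    return(list(p_combined = pvals[1], psi = -2 * log(pvals[1]),
                scale_c = 1, df_f = 2))
  }
  if (n < 10) stop("need at least 10 samples to estimate dependence")
  w <- t(apply(data, 1, function(row) {
    fhat <- (rank(row) - 0.5) / length(row)
    -2 * log(1 - fhat)
  }))
  cv <- stats::cov(t(w))
  sum_cov <- sum(cv[upper.tri(cv)])
  e <- 2 * k
  v <- 4 * k + 2 * sum_cov
  v <- max(v, .Machine$double.eps)
  f <- 2 * e^2 / v
  c_scale <- v / (2 * e)
  psi <- -2 * sum(log(pvals))
  p <- pchisq(psi / c_scale, df = f, lower.tail = FALSE)
  list(p_combined = max(p, .Machine$double.xmin), psi = psi,
       scale_c = c_scale, df_f = f)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return vector of q-values in the input order.
#' @export
bh_correct <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  p.adjust(pvals, method = "BH")
}

#' Cluster-level association summary
#'
#' Aggregates per-HIF correlation results to HIF clusters: the median
#' absolute Spearman rho across member features, the Brown-combined p-value
#' over the member p-values (dependence estimated from the member HIF
#' values), and BH correction across clusters. Singleton clusters pass their
#' member p through.
#'
#' @param per_hif result of [spearman_assoc()].
#' @param clusters a [cluster_hifs()] result.
#' @param hm the `hif_matrix` the correlations were computed on.
#' @return data frame with `cluster_id`, `n_members`, `median_abs_rho`,
#'   `p_brown`, `q`.
#' @export
cluster_assoc_summary <- function(per_hif, clusters, hm) {
  ids <- sort(unique(clusters$assignment))
  rows <- lapply(ids, function(cl) {
    members <- names(clusters$assignment)[clusters$assignment == cl]
    sub <- per_hif[match(members, per_hif$feature_id), ]
    ok <- !is.na(sub$p)
    if (!any(ok)) {
      return(data.frame(cluster_id = cl, n_members = length(members),
                        median_abs_rho = NA_real_, p_brown = NA_real_))
    }
    br <- empirical_browns(t(hm$values[, sub$feature_id[ok], drop = FALSE]),
                           sub$p[ok])
    data.frame(cluster_id = cl, n_members = length(members),
               median_abs_rho = median(abs(sub$rho), na.rm = TRUE),
               p_brown = br$p_combined)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_correct(out$p_brown)
  out
}

#' Group differences in Z-scored HIFs
#'
#' For each group label and feature: the median Z-score within the group,
#' and a one-sided Mann-Whitney U test of that group against the pooled
#' remaining samples (`alternative` applies to the named group).
#'
#' @param hm a pan-cohort z-scored `hif_matrix`.
#' @param groups vector of group labels aligned to rows.
#' @param features feature ids to test (default: all columns).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return data frame with `group`, `feature_id`, `median_z`, `U`, `p`.
#' @export
group_difference <- function(hm, groups, features = colnames(hm$values),
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(groups) == nrow(hm$values))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  rows <- list()
  for (g in names(tab)) {
    sel <- groups == g
    if (sum(sel) < 3 || sum(!sel) < 3) next
    for (f in features) {
      x <- hm$values[sel, f]
      y <- hm$values[!sel, f]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                         exact = FALSE, correct = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, feature_id = f, median_z = median(x),
        U = unname(wt$statistic), p = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
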