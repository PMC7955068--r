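#' Permutation inference for ensemble betas
#'
#' Builds a null distribution of ensemble coefficients by permuting the
#' training labels `B` times and re-running the entire nested-CV + ensembling
#' process per permutation. Per-HIF two-sided p-values use add-one smoothing,
#' `p = (1 + #{|beta_null| >= |beta_obs|}) / (B + 1)`, so no p falls below
#' `1/(B+1)`. Per-HIF p-values are combined into HIF-cluster p-values with
#' the Empirical Brown's method (dependence estimated from the member HIF
#' values) and BH-corrected across clusters.
#'
#' @param X,y,groups the training design the ensemble was fitted on.
#' @param ensemble the observed [nested_cv_ensemble()] fit.
#' @param B number of permutations (values below 50 warn: unstable tail).
#' @param seed RNG seed.
#' @param config a [hif_config()].
#' @return list with `p_hif` (named), `cluster_table` (cluster_id, p_brown,
#'   q), `B`.
#' @export
permutation_beta_inference <- function(X, y, groups, ensemble, B = 1000,
                                       seed = 1, config = hif_config()) {
  if (B < 50) warning("B < 50 permutations gives an unstable null tail")
  X <- as.matrix(X)
  beta_obs <- abs(ensemble$beta)
  exceed <- numeric(ncol(X))
  set.seed(seed)
  perm_seeds <- sample.int(2147483646L, B)
  for (b in seq_len(B)) {
    set.seed(perm_seeds[b])
    yp <- sample(y)
    ens_b <- nested_cv_ensemble(X, yp, groups, seed = perm_seeds[b],
                                config = config, tol = 1e-5)
    exceed <- exceed + (abs(ens_b$beta) >= beta_obs)
  }
  p_hif <- setNames((1 + exceed) / (B + 1), colnames(X))
  gidx <- groups
  ids <- sort(unique(gidx))
  rows <- lapply(ids, function(cl) {
    members <- which(gidx == cl)
    p_cl <- if (length(members) == 1) {
      p_hif[members]
    } else {
      empirical_browns(t(X[, members, drop = FALSE]), p_hif[members])$p_combined
    }
    data.frame(cluster_id = cl, n_members = length(members),
               max_abs_beta = max(beta_obs[members]), p_brown = unname(p_cl))
  })
  cluster_table <- do.call(rbind, rows)
  cluster_table$q <- bh_correct(cluster_table$p_brown)
  list(p_hif = p_hif, cluster_table = cluster_table, B = B)
}
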