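#' Nested cross-validated sparse-group-lasso ensemble
#'
#' Stratified 3-fold outer split; for each outer training set (two folds), a
#' 5-fold inner cross-validation selects the penalty `lambda` over a 30-point
#' log grid descending three decades from that training set's `lambda_max`,
#' by mean inner-fold AUROC (ties resolve to the larger, sparser lambda). The
#' three tuned models, each refit on its outer training set, are ensembled by
#' averaging predicted probabilities; ensemble betas are the arithmetic mean
#' of the three coefficient vectors. A fold draw that leaves any fold
#' single-class is re-stratified with a fresh seed (up to 10 attempts).
#'
#' @param X z-scored feature matrix.
#' @param y binary 0/1 labels (both classes with count >= 6).
#' @param groups group label per column (HIF cluster ids).
#' @param seed RNG seed controlling the fold draws.
#' @param config a [hif_config()] (folds, grid shape, alpha).
#' @param tol,max_iter solver controls for the final outer-fold refits.
#' @param inner_tol,inner_max_iter looser solver controls for the inner
#'   tuning fits, whose only job is to rank lambdas by AUROC.
#' @return object of class `sgl_ensemble`: `models` (3 `sgl_model`s),
#'   `beta` (ensemble), `intercepts`, `lambda` (per fold), `outer_folds`.
#' @export
nested_cv_ensemble <- function(X, y, groups, seed = 1, config = hif_config(),
                               tol = 1e-6, max_iter = 2000,
                               inner_tol = 1e-4, inner_max_iter = 150) {
  X <- as.matrix(X)
  if (min(table(factor(y, levels = 0:1))) < 6)
    stop("each class needs at least 6 observations")
  k_out <- config$n_outer_folds
  k_in <- config$n_inner_folds
  folds <- stratified_folds_safe(y, k_out, seed)
  models <- vector("list", k_out)
  lambdas_sel <- numeric(k_out)
  for (k in seq_len(k_out)) {
    tr <- folds != k
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    lam_max <- sgl_lambda_max(Xtr, ytr, groups, config$sgl_alpha)
    grid <- 10^seq(log10(lam_max), log10(lam_max) - config$lambda_decades,
                   length.out = config$lambda_grid_size)
    inner <- stratified_folds_safe(ytr, k_in, derive_seed(seed, 131 + k))
    auc <- matrix(NA_real_, k_in, length(grid))
    for (j in seq_len(k_in)) {
      itr <- inner != j
      fits <- sgl_path(Xtr[itr, , drop = FALSE], ytr[itr], groups, grid,
                       alpha = config$sgl_alpha, tol = inner_tol,
                       max_iter = inner_max_iter)
      for (l in seq_along(grid)) {
        pr <- predict(fits[[l]], Xtr[!itr, , drop = FALSE])
        auc[j, l] <- auroc(pr, ytr[!itr])
      }
    }
    mean_auc <- colMeans(auc)
    sel <- which.max(mean_auc) # first max = largest lambda on ties
    lambdas_sel[k] <- grid[sel]
    # cheap warm-start path on the outer training set, then one fit at the
    # selected lambda at the tight tolerance
    warm <- sgl_path(Xtr, ytr, groups, grid[seq_len(sel)],
                     alpha = config$sgl_alpha, tol = inner_tol,
                     max_iter = inner_max_iter)
    models[[k]] <- fit_sgl_logistic(
      Xtr, ytr, groups, grid[sel], alpha = config$sgl_alpha, tol = tol,
      max_iter = max_iter,
      init = list(beta = warm[[sel]]$beta, intercept = warm[[sel]]$intercept))
  }
  beta <- rowMeans(vapply(models, function(m) m$beta, numeric(ncol(X))))
  structure(list(models = models, beta = setNames(beta, colnames(X)),
                 intercepts = vapply(models, function(m) m$intercept, 1.0),
                 lambda = lambdas_sel, outer_folds = folds,
                 alpha = config$sgl_alpha),
            class = "sgl_ensemble")
}

#' @export
print.sgl_ensemble <- function(x, ...) {
  cat(sprintf("<sgl_ensemble> 3 models, lambda = (%s), %d/%d nonzero ensemble betas\n",
              paste(signif(x$lambda, 3), collapse = ", "),
              sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' @export
predict.sgl_ensemble <- function(object, newdata, ...) {
  probs <- vapply(object$models, function(m) predict(m, newdata),
                  numeric(nrow(as.matrix(newdata))))
  rowMeans(matrix(probs, ncol = length(object$models)))
}

# derived seed kept inside the 32-bit integer range
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 7919) %% 2147483647)
}

# stratified fold assignment; retries until every fold holds both classes
stratified_folds_safe <- function(y, k, seed, max_attempts = 10) {
  for (attempt in seq_len(max_attempts)) {
    set.seed(derive_seed(seed, attempt))
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    ok <- all(vapply(seq_len(k), function(j) {
      length(unique(y[folds == j])) == 2
    }, TRUE))
    if (ok) return(folds)
  }
  stop("could not stratify folds with both classes present")
}
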