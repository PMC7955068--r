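test_that("GMM binarization recovers analytic density intersections", {
  set.seed(1)
  v <- c(rnorm(1000, 0, 1), rnorm(1000, 6, 1))
  b <- gmm_binarize(v)
  expect_lt(abs(b$threshold - 3), 0.15) # symmetric case: midpoint
  expect_equal(b$labels, as.integer(v >= b$threshold))
  expect_true(b$mu[1] <= b$threshold && b$threshold <= b$mu[2])

  # unequal variances: compare to the weighted-density crossing found
  # independently by root-solving the density difference
  set.seed(2)
  v2 <- c(rnorm(1500, 0, 1), rnorm(1500, 6, 2))
  b2 <- gmm_binarize(v2)
  root <- uniroot(function(x) 0.5 * dnorm(x, 0, 1) - 0.5 * dnorm(x, 6, 2),
                  c(0.5, 5.5))$root
  expect_lt(abs(b2$threshold - root), 0.2)

  expect_error(gmm_binarize(rep(2, 50)), "constant")
  expect_error(gmm_binarize(rnorm(10)), "at least 20")
})

test_that("site hold-out splits are site-disjoint and in range", {
  meta <- data.frame(patient_id = sprintf("p%03d", 1:100),
                     site_id = rep(sprintf("s%02d", 1:10), each = 10))
  for (seed in 1:10) {
    sp <- site_holdout_split(meta, seed = seed)
    expect_gte(sp$holdout_frac, 0.2)
    expect_lte(sp$holdout_frac, 0.3)
    ts <- unique(meta$site_id[meta$patient_id %in% sp$train])
    hs <- unique(meta$site_id[meta$patient_id %in% sp$holdout])
    expect_length(intersect(ts, hs), 0)
    expect_setequal(c(sp$train, sp$holdout), meta$patient_id)
  }
  # deterministic per seed
  expect_identical(site_holdout_split(meta, seed = 3),
                   site_holdout_split(meta, seed = 3))
  # degenerate: two half-cohort sites cannot reach 20-30%
  meta2 <- data.frame(patient_id = paste0("p", 1:20),
                      site_id = rep(c("a", "b"), each = 10))
  expect_warning(sp2 <- site_holdout_split(meta2, seed = 1), "no site subset")
  expect_equal(sp2$holdout_frac, 0.5)
})

test_that("the SGL solver matches unpenalized logistic regression at lambda 0", {
  set.seed(3)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- rbinom(n, 1, plogis(0.5 + drop(X %*% c(1, -1, 0.5, 0, 0))))
  fit <- fit_sgl_logistic(X, y, c(1, 1, 2, 2, 3), lambda = 0,
                          tol = 1e-9, max_iter = 50000)
  ref <- glm(y ~ X, family = binomial)
  expect_lt(max(abs(fit$beta - coef(ref)[-1])), 1e-4)
  expect_lt(abs(fit$intercept - coef(ref)[1]), 1e-4)
  expect_error(fit_sgl_logistic(X, y + 1, c(1, 1, 2, 2, 3), 0.1), "binary")
  expect_error(fit_sgl_logistic(X, y, c(1, 1, 2, 2, 3), -1), "non-negative")
})

test_that("lambda_max zeroes the model and the objective is monotone", {
  set.seed(4)
  n <- 150
  X <- matrix(rnorm(n * 12), n, 12)
  colnames(X) <- paste0("f", 1:12)
  groups <- rep(1:4, each = 3)
  y <- rbinom(n, 1, plogis(drop(X %*% rnorm(12, 0, 0.5))))
  lmax <- sgl_lambda_max(X, y, groups)
  at <- fit_sgl_logistic(X, y, groups, lmax * 1.0001)
  expect_true(all(at$beta == 0))
  below <- fit_sgl_logistic(X, y, groups, lmax * 0.9)
  expect_true(any(below$beta != 0))
  expect_true(all(diff(below$objective) <= 1e-8))
})

test_that("SGL recovers a single active group along the mid-path", {
  set.seed(5)
  n <- 400; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  groups <- rep(1:4, each = 5)
  beta_true <- c(rnorm(5, 0, 1.2), rep(0, 15)) # group 1 active
  y <- rbinom(n, 1, plogis(drop(X %*% beta_true)))
  lmax <- sgl_lambda_max(X, y, groups)
  fit <- fit_sgl_logistic(X, y, groups, lmax * 0.3)
  expect_true(any(fit$beta[1:5] != 0))
  expect_true(all(fit$beta[6:20] == 0))
})

test_that("screened and unscreened paths agree", {
  set.seed(6)
  n <- 120; p <- 30
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
  groups <- rep(1:6, each = 5)
  y <- rbinom(n, 1, plogis(drop(X %*% c(rnorm(10), rep(0, 20)))))
  lmax <- sgl_lambda_max(X, y, groups)
  grid <- 10^seq(log10(lmax), log10(lmax) - 2, length.out = 8)
  f1 <- sgl_path(X, y, groups, grid, screen = TRUE, tol = 1e-7)
  f0 <- sgl_path(X, y, groups, grid, screen = FALSE, tol = 1e-7)
  for (i in seq_along(grid)) {
    expect_lt(max(abs(f1[[i]]$beta - f0[[i]]$beta)), 1e-4)
  }
})

test_that("the nested-CV ensemble averages betas and probabilities", {
  set.seed(7)
  n <- 90; p <- 12
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
  groups <- rep(1:4, each = 3)
  y <- rbinom(n, 1, plogis(drop(X %*% c(2, 2, 2, rep(0, 9)))))
  ens <- nested_cv_ensemble(X, y, groups, seed = 2)
  bmat <- vapply(ens$models, function(m) m$beta, numeric(p))
  expect_equal(unname(ens$beta), unname(rowMeans(bmat)))
  pr <- predict(ens, X[1:5, ])
  pmat <- vapply(ens$models, function(m) predict(m, X[1:5, ]), numeric(5))
  expect_equal(pr, rowMeans(pmat))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(nested_cv_ensemble(X[1:10, ], c(1, rep(0, 9)), groups),
               "at least 6")
})

test_that("permuted labels give chance-level discrimination", {
  set.seed(8)
  n <- 180; p <- 10
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
  groups <- rep(1:2, each = 5)
  aucs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    y <- sample(rep(0:1, n / 2))
    ens <- nested_cv_ensemble(X[1:120, ], y[1:120], groups, seed = s)
    auroc(predict(ens, X[121:180, ]), y[121:180])
  }, 1.0)
  expect_true(all(aucs > 0.28 & aucs < 0.72))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("AUROC/AUPRC match exhaustive pair counting and are rank-based", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  s <- c(0.1, 0.4, 0.35, 0.8); l <- c(0, 0, 1, 1)
  expect_equal(auroc(qlogis(s), l), auroc(s, l)) # monotone invariance
  expect_equal(auroc(rep(0.5, 4), c(0, 1, 0, 1)), 0.5) # all tied
  # AUPRC by hand for scores 0.9(1), 0.8(0), 0.3(1), 0.2(0):
  # recall steps at ranks 1 and 3 with precisions 1 and 2/3
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
})

test_that("bootstrap evaluation yields sane intervals and p-values", {
  set.seed(9)
  n <- 80
  labels <- rep(0:1, n / 2)
  perfect <- labels + rnorm(n, 0, 1e-6)
  ev <- evaluate_predictions(perfect, labels, n_boot = 200, seed = 1)
  expect_equal(ev$auroc, 1)
  expect_equal(ev$auroc_p, 0) # a perfect classifier never dips below 0.5
  noisy <- rnorm(n)
  ev2 <- evaluate_predictions(noisy, labels, n_boot = 200, seed = 1)
  expect_true(ev2$auroc_ci[1] <= ev2$auroc && ev2$auroc <= ev2$auroc_ci[2])
  expect_error(evaluate_predictions(noisy, rep(1, n)), "both classes")
})

test_that("permutation p-values are bounded and flag planted signal", {
  set.seed(10)
  n <- 150; p <- 6
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
  groups <- rep(1:3, each = 2)
  y <- as.integer(X[, 1] + rnorm(n, 0, 0.1) > 0)
  ens <- nested_cv_ensemble(X, y, groups, seed = 1)
  B <- 29
  res <- suppressWarnings(
    permutation_beta_inference(X, y, groups, ens, B = B, seed = 2))
  expect_true(all(res$p_hif >= 1 / (B + 1)))
  expect_true(all(res$p_hif <= 1))
  expect_equal(unname(res$p_hif["f1"]), 1 / (B + 1))
  expect_equal(res$cluster_table$q, bh_correct(res$cluster_table$p_brown))
  expect_warning(permutation_beta_inference(X, y, groups, ens, B = 10,
                                            seed = 1), "unstable")
})
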