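make_hm <- function(vals) {
  n <- nrow(vals)
  meta <- data.frame(slide_id = paste0("p", 1:n), patient_id = paste0("p", 1:n),
                     site_id = "s", cancer_type = "t")
  hif_matrix(vals, meta)
}

test_that("Spearman association is a rank statistic with the t-approximate p", {
  set.seed(1)
  n <- 40
  x <- rnorm(n)
  vals <- cbind(mono = exp(x), neg = -x, noise = rnorm(n), flat = rep(1, n))
  res <- spearman_assoc(make_hm(vals), x)
  expect_equal(res$rho[res$feature_id == "mono"], 1)
  expect_equal(res$rho[res$feature_id == "neg"], -1)
  expect_true(is.na(res$rho[res$feature_id == "flat"]))
  expect_equal(res$p[res$feature_id == "mono"], 0)

  # closed-form oracle on tie-free n = 8 vectors
  set.seed(3)
  a <- sample(100, 8); b <- sample(100, 8)
  r8 <- spearman_assoc(make_hm(cbind(f = a)), b)
  d <- rank(a) - rank(b)
  rho_oracle <- 1 - 6 * sum(d^2) / (8 * (8^2 - 1))
  expect_equal(r8$rho, rho_oracle, tolerance = 1e-12)
  t_oracle <- rho_oracle * sqrt(6 / (1 - rho_oracle^2))
  expect_equal(r8$p, 2 * pt(-abs(t_oracle), 6), tolerance = 1e-12)
})

test_that("Empirical Brown reduces to Fisher under independence", {
  expect_equal(empirical_browns(matrix(rnorm(20), 2), c(1, 1))$p_combined, 1)
  set.seed(4)
  k <- 6; n <- 500
  dat <- matrix(rnorm(k * n), k, n)
  ps <- runif(k, 0.01, 0.9)
  br <- empirical_browns(dat, ps)
  fisher <- pchisq(-2 * sum(log(ps)), 2 * k, lower.tail = FALSE)
  expect_equal(br$p_combined, fisher, tolerance = 0.12 * fisher + 0.01)
  expect_equal(br$df_f, 2 * k, tolerance = 0.15 * 2 * k)
  expect_equal(br$scale_c, 1, tolerance = 0.15)
})

test_that("full dependence collapses the combined evidence toward p0", {
  set.seed(6)
  n <- 400
  v <- rnorm(n)
  dat <- matrix(rep(v, 5), 5, byrow = TRUE) # identical variables
  p0 <- 0.02
  br <- empirical_browns(dat, rep(p0, 5))
  expect_equal(br$p_combined, p0, tolerance = 0.5)
  # p floor: zeros are clamped, result stays in (0, 1]
  br0 <- empirical_browns(matrix(rnorm(40), 2), c(0, 1e-40))
  expect_gt(br0$p_combined, 0)
})

test_that("BH correction matches the hand step-up computation", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_correct(0.07), 0.07)
  expect_equal(bh_correct(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_correct(p), oracle_bh(p))
  # order invariance
  ord <- sample(50)
  expect_equal(bh_correct(p[ord]), oracle_bh(p)[ord])
})

test_that("cluster association summaries aggregate correctly", {
  set.seed(5)
  n <- 60
  sig <- rnorm(n)
  vals <- cbind(a1 = sig + rnorm(n, 0, 0.5), a2 = -sig + rnorm(n, 0, 0.5),
                b1 = rnorm(n))
  hm <- make_hm(vals)
  per_hif <- spearman_assoc(hm, sig)
  clusters <- list(assignment = c(a1 = 1L, a2 = 1L, b1 = 2L), n_clusters = 2L,
                   cutoff = 0.95)
  out <- cluster_assoc_summary(per_hif, clusters, hm)
  expect_equal(out$median_abs_rho[out$cluster_id == 1],
               median(abs(per_hif$rho[1:2])))
  # singleton cluster passes its p through
  expect_equal(out$p_brown[out$cluster_id == 2], per_hif$p[3])
  expect_equal(out$q, bh_correct(out$p_brown))
  expect_lt(out$p_brown[1], out$p_brown[2]) # signal cluster more significant
})

test_that("group differences detect a shifted group and report U exactly", {
  set.seed(7)
  vals <- cbind(f = c(rnorm(100) + 1, rnorm(100)))
  hm <- make_hm(vals)
  res <- group_difference(hm, rep(c("g1", "g2"), each = 100))
  r1 <- res[res$group == "g1", ]
  expect_gt(r1$median_z, 0)
  expect_lt(r1$p, 0.05)
  # exhaustive toy: {1,2} vs {3,4} -> U = 0
  w <- suppressWarnings(wilcox.test(c(1, 2), c(3, 4), alternative = "less",
                                    exact = FALSE))
  expect_equal(unname(w$statistic), 0)
  # null: identical groups give median Z near 0
  vals0 <- cbind(f = rnorm(200))
  res0 <- group_difference(make_hm(vals0), rep(c("a", "b"), 100))
  expect_lt(max(abs(res0$median_z)), 0.5)
})
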