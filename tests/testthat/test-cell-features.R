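test_that("proximity counts respect the radius boundary exactly", {
  expect_equal(proximity_pair_count(0, 0, 0, 79), 1L)
  expect_equal(proximity_pair_count(0, 0, 0, 80), 1L)
  expect_equal(proximity_pair_count(0, 0, 0, 81), 0L)
  expect_equal(proximity_pair_count(numeric(0), numeric(0), 1, 1), 0L)
  expect_equal(proximity_pair_count(1:5, rep(0, 5), 1:5, rep(0, 5)), 5L)
})

test_that("proximity counts equal the all-pairs oracle on random scenes", {
  for (seed in 1:8) {
    set.seed(seed)
    na <- 200; nb <- 180
    ax <- runif(na, 0, 600); ay <- runif(na, 0, 600)
    bx <- runif(nb, 0, 600); by <- runif(nb, 0, 600)
    r <- runif(1, 20, 120)
    expect_equal(proximity_pair_count(ax, ay, bx, by, r),
                 oracle_prox_count(ax, ay, bx, by, r))
  }
})

test_that("birch clustering handles degenerate and separable inputs", {
  one <- birch_clusters(5, 7)
  expect_equal(one$K, 1)
  expect_equal(one$size, 1L)
  expect_equal(one$extent, 0)
  expect_equal(one$dispersion, 0)

  same <- birch_clusters(rep(3, 10), rep(4, 10))
  expect_equal(same$K, 1)
  expect_equal(same$dispersion, 0)

  set.seed(2)
  x <- c(rnorm(40, 0, 10), rnorm(40, 1000, 10))
  y <- rnorm(80, 0, 10)
  cl <- birch_clusters(x, y, threshold = 100, branching = 10)
  expect_equal(cl$K, 2)
  expect_true(all(cl$assignment[1:40] == cl$assignment[1]))
  expect_true(all(cl$assignment[41:80] == cl$assignment[41]))
  expect_false(cl$assignment[1] == cl$assignment[41])
  expect_equal(sum(cl$size), 80)
  expect_true(all(cl$extent >= cl$dispersion))
})

test_that("cluster indices match hand computation on the toy partition", {
  # two clusters: (0,0),(0,2) and (100,0),(100,2)
  x <- c(0, 0, 100, 100); y <- c(0, 2, 0, 2)
  idx <- cluster_indices(x, y, c(1, 1, 2, 2))
  expect_equal(idx$ball_hall, 1.0) # each cluster: mean squared dist 1^2
  expect_equal(idx$calinski_harabasz, (2 * 50^2 * 2 / 1) / (4 / 2))
  one <- cluster_indices(x, y, rep(1, 4))
  expect_true(is.na(one$calinski_harabasz))
  singletons <- cluster_indices(x, y, 1:4)
  expect_true(is.na(singletons$calinski_harabasz)) # N == K
  expect_equal(singletons$ball_hall, 0)
})

test_that("cluster features are translation invariant and conserve counts", {
  set.seed(4)
  r <- matrix(1L, 50, 50)
  n <- 120
  cells <- data.frame(x_um = runif(n, 0, 200), y_um = runif(n, 0, 200),
                      cell_class = "lymphocyte")
  s1 <- slide_map(r, cells, mpp = 4)
  f1 <- cluster_features(s1)
  # translating the points (and window) leaves every metric unchanged
  big <- matrix(1L, 80, 80)
  cells2 <- data.frame(x_um = cells$x_um + 100, y_um = cells$y_um + 100,
                       cell_class = "lymphocyte")
  f2 <- cluster_features(slide_map(big, cells2, mpp = 4))
  keys <- paste("clust_lymphocyte",
                c("n_clusters", "size_mean", "size_sd", "dispersion_mean",
                  "dispersion_sd", "extent_mean", "extent_sd", "ball_hall",
                  "calinski_harabasz"), "ct", sep = "_")
  expect_equal(f1[keys], f2[keys], tolerance = 1e-9)
  cl <- birch_clusters(cells$x_um, cells$y_um)
  expect_equal(sum(cl$size), n)
  expect_equal(unname(f1["clust_lymphocyte_n_clusters_ct"]), cl$K)
})

test_that("count/density features follow the membership oracle", {
  for (seed in 1:4) {
    s <- random_slide(seed, n = 48, n_cells = 120)
    f <- count_density_features(s)
    px <- cbind(floor(s$cells$y_um / s$mpp) + 1, floor(s$cells$x_um / s$mpp) + 1)
    code <- s$raster[px]
    for (cls in c("lymphocyte", "cancer")) {
      in_ct <- sum(code == 1 & s$cells$cell_class == cls)
      in_cas <- sum(code == 2 & s$cells$cell_class == cls)
      expect_equal(unname(f[paste0("cd_", cls, "_count_ct")]), in_ct)
      expect_equal(unname(f[paste0("cd_", cls, "_count_cas")]), in_cas)
      expect_equal(unname(f[paste0("cd_", cls, "_count_ct_cas")]), in_ct + in_cas)
    }
    ct_area <- sum(s$raster == 1) * (s$mpp / 1000)^2
    if (ct_area > 0) {
      expect_equal(unname(f["cd_total_density_ct"]),
                   sum(code == 1) / ct_area)
    }
  }
})

test_that("proportion features are ratios with missing on empty denominators", {
  r <- matrix(1L, 20, 20)
  cells <- data.frame(x_um = runif(30, 0, 80), y_um = runif(30, 0, 80),
                      cell_class = "lymphocyte")
  s <- slide_map(r, cells, mpp = 4)
  f <- proportion_proximity_features(s)
  expect_equal(unname(f["pp_prop_lymphocyte_ct"]), 1)
  expect_equal(unname(f["pp_prop_cancer_ct"]), 0)
  expect_true(is.na(f["pp_prop_lymphocyte_cas"])) # no CAS cells
  # proportional count a/(a+b): 30 lymphocytes, 0 fibroblasts
  expect_equal(unname(f["pp_pairprop_lymphocyte_fibroblast_ct"]), 1)
  # all-normal slide: everything missing or zero
  s0 <- slide_map(matrix(0L, 10, 10), mpp = 4)
  f0 <- proportion_proximity_features(s0)
  expect_true(all(is.na(f0) | f0 == 0))
})

test_that("interface proximity features equal a brute-force distance test", {
  s <- half_half_slide(n = 30, mpp = 4,
                       cells = data.frame(
                         x_um = runif(80, 0, 120), y_um = runif(80, 0, 120),
                         cell_class = rep(c("lymphocyte", "fibroblast"), 40)))
  f <- proportion_proximity_features(s)
  iface <- csi_interface(s)
  d <- sapply(seq_len(nrow(s$cells)), function(i) {
    min(sqrt((iface$edge_x - s$cells$x_um[i])^2 +
               (iface$edge_y - s$cells$y_um[i])^2))
  })
  near <- d <= 80
  is_l <- s$cells$cell_class == "lymphocyte"
  expect_equal(unname(f["pp_iface_lymphocyte_count"]), sum(near & is_l))
  expect_equal(unname(f["pp_far_lymphocyte_count"]), sum(!near & is_l))
  expect_equal(unname(f["pp_iface_total_count"]), sum(near))
})
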