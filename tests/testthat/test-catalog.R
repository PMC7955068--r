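test_that("the catalog manifest reproduces the published totals", {
  m <- hif_manifest()
  expect_equal(nrow(m), 607)
  counts <- table(m$category)
  expect_equal(unname(counts[["count_density"]]), 56)
  expect_equal(unname(counts[["cluster"]]), 180)
  expect_equal(unname(counts[["proportion_proximity"]]), 208)
  expect_equal(unname(counts[["area_multiplicity"]]), 13)
  expect_equal(unname(counts[["architecture"]]), 25)
  expect_equal(unname(counts[["morphology"]]), 125)
  tissue <- sum(m$category %in% c("area_multiplicity", "architecture", "morphology"))
  expect_equal(tissue, 163)
  expect_equal(607 - tissue, 444)
  expect_equal(sum(m$category %in% c("count_density", "proportion_proximity")), 264)
  expect_false(anyDuplicated(m$feature_id) > 0)
})

test_that("extract_slide composes the per-family feature functions", {
  s <- random_slide(21, n = 48, n_cells = 150)
  row <- extract_slide(s)
  expect_equal(length(row), 607)
  direct <- c(area_multiplicity_features(s), morphology_features(s),
              architecture_features(s), count_density_features(s),
              proportion_proximity_features(s), cluster_features(s))
  expect_equal(row, direct[names(row)])
  expect_identical(row, extract_slide(s)) # deterministic
})

test_that("an all-normal slide yields missing regional features, zero counts", {
  s <- slide_map(matrix(0L, 24, 24), mpp = 4)
  row <- extract_slide(s)
  expect_equal(unname(row["area_mm2_ct"]), 0)
  expect_equal(unname(row["cd_lymphocyte_count_ct"]), 0)
  expect_true(is.na(row["morph_eccentricity_largest_ct"]))
  expect_true(is.na(row["cd_lymphocyte_density_ct"]))
  expect_true(is.na(row["clust_cancer_size_mean_ct_cas"]))
})

test_that("patient aggregation selects the slide with the largest CT+CAS area", {
  vals <- matrix(0, 5, 607, dimnames = list(
    c("a-s1", "a-s2", "b-s1", "c-s1", "c-s2"), hif_manifest()$feature_id))
  vals[, "area_mm2_ct_cas"] <- c(1.0, 2.5, 3.0, 1.5, 1.5)
  vals[, "cd_total_count_ct"] <- 1:5
  meta <- data.frame(slide_id = rownames(vals),
                     patient_id = c("a", "a", "b", "c", "c"),
                     site_id = "s", cancer_type = "x")
  hm <- hif_matrix(vals, meta)
  pat <- aggregate_patients(hm)
  expect_equal(rownames(pat$values), c("a", "b", "c"))
  expect_equal(unname(pat$values[, "cd_total_count_ct"]), c(2, 3, 4))
  # ties break to the smaller slide id ("c-s1"); single slides pass through
  expect_equal(pat$meta$slide_id, c("a-s2", "b-s1", "c-s1"))
  # idempotence
  expect_identical(aggregate_patients(pat)$values, pat$values)
})

test_that("z-scoring matches the closed form and is idempotent", {
  vals <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(2, NA, 4))
  vals <- cbind(vals, matrix(rnorm(3 * 604), 3,
                             dimnames = list(NULL, paste0("x", 1:604))))
  meta <- data.frame(slide_id = letters[1:3], patient_id = letters[1:3],
                     site_id = "s", cancer_type = "t")
  hm <- zscore_hifs(hif_matrix(vals, meta))
  expect_equal(unname(hm$values[, "f1"]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(unname(hm$values[, "f2"]), c(0, 0, 0)) # constant -> 0
  expect_equal(unname(hm$values[2, "f3"]), 0)         # missing -> cohort mean
  # idempotence on complete columns (imputed entries join the cohort on the
  # second pass, so the property is stated for complete data)
  complete <- hm$values[, setdiff(colnames(hm$values), "f3")]
  hm2 <- zscore_hifs(hif_matrix(complete, meta))
  expect_equal(hm2$values, complete, tolerance = 1e-9)
  # non-constant columns have mean 0 and population SD 1
  expect_lt(max(abs(colMeans(hm$values))), 1e-9)
  sds <- apply(hm$values, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(unname(sds[c("f1", "x1")]), c(1, 1), tolerance = 1e-9)
  expect_error(zscore_hifs(hif_matrix(vals[1, , drop = FALSE], meta[1, ])),
               "at least two rows")
})

test_that("HIF clustering groups duplicates and splits independent noise", {
  set.seed(8)
  n <- 4000
  base <- rnorm(n)
  vals <- cbind(a = base, b = 3 * base + 2, # rank-identical -> distance 0
                c = rnorm(n), d = rnorm(n)) # independent -> distance ~ 1
  meta <- data.frame(slide_id = paste0("p", 1:n), patient_id = paste0("p", 1:n),
                     site_id = "s", cancer_type = "t")
  cl <- cluster_hifs(hif_matrix(vals, meta), cutoff = 0.95)
  expect_equal(cl$assignment[["a"]], cl$assignment[["b"]])
  expect_false(cl$assignment[["c"]] == cl$assignment[["d"]])
  expect_false(cl$assignment[["a"]] == cl$assignment[["c"]])
})

test_that("HIF clustering agrees with a brute-force complete-linkage oracle", {
  set.seed(12)
  n <- 60
  z <- rnorm(n)
  vals <- cbind(f1 = z + rnorm(n, 0, 0.1), f2 = -z + rnorm(n, 0, 0.1),
                f3 = rnorm(n), f4 = rnorm(n), f5 = z + rnorm(n, 0, 2))
  meta <- data.frame(slide_id = paste0("p", 1:n), patient_id = paste0("p", 1:n),
                     site_id = "s", cancer_type = "t")
  hm <- hif_matrix(vals, meta)
  got <- cluster_hifs(hm, cutoff = 0.6)$assignment
  d <- 1 - abs(cor(vals, method = "spearman"))
  diag(d) <- 0
  want <- oracle_complete_linkage(d, 0.6)
  # same partition up to label renaming
  expect_equal(length(unique(got)), length(unique(want)))
  expect_true(all(outer(got, got, "==") == outer(want, want, "==")))
  # complete-linkage guarantee: within-cluster distances below the cutoff
  for (cl in unique(got)) {
    sel <- got == cl
    if (sum(sel) > 1) expect_lte(max(d[sel, sel]), 0.6)
  }
})
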