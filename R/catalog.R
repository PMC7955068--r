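#' Extract the full HIF row for one slide
#'
#' Computes all 607 features in manifest order from one slide map. Features
#' undefined on the slide (empty regions, zero denominators, degenerate
#' geometry) are `NA`, the catalog's missing sentinel; they are imputed only
#' after Z-scoring (see [zscore_hifs()]).
#'
#' @param slide a [slide_map()].
#' @param manifest a [hif_manifest()].
#' @param config a [hif_config()].
#' @return named numeric vector of length `nrow(manifest)`.
#' @export
extract_slide <- function(slide, manifest = hif_manifest(config),
                          config = hif_config()) {
  ctx <- slide_context(slide, config)
  vals <- c(area_features_ctx(ctx),
            morphology_features_ctx(ctx),
            architecture_features_ctx(ctx),
            count_density_ctx(ctx),
            proportion_proximity_ctx(ctx),
            cluster_features_ctx(ctx))
  if (!identical(names(vals), manifest$feature_id))
    stop("extracted feature names do not match the manifest")
  vals
}

#' Extract a slide-level HIF matrix for a list of slides
#'
#' @param slides list of [slide_map()] objects.
#' @param manifest,config see [extract_slide()].
#' @param verbose print progress every 25 slides.
#' @return a `hif_matrix` (slides x features) with slide/patient/site
#'   metadata attached; see [hif_matrix()].
#' @export
extract_cohort <- function(slides, manifest = hif_manifest(config),
                           config = hif_config(), verbose = FALSE) {
  vals <- matrix(NA_real_, length(slides), nrow(manifest),
                 dimnames = list(vapply(slides, function(s) s$slide_id, ""),
                                 manifest$feature_id))
  for (i in seq_along(slides)) {
    vals[i, ] <- extract_slide(slides[[i]], manifest, config)
    if (verbose && i %% 25 == 0) message("extracted ", i, "/", length(slides))
  }
  meta <- data.frame(
    slide_id = vapply(slides, function(s) s$slide_id, ""),
    patient_id = vapply(slides, function(s) s$patient_id, ""),
    site_id = vapply(slides, function(s) s$site_id, ""),
    cancer_type = vapply(slides, function(s) s$cancer_type, ""),
    stringsAsFactors = FALSE)
  hif_matrix(vals, meta)
}

#' HIF matrix container
#'
#' A numeric matrix of feature values (rows = slides or patients, columns =
#' manifest order) carrying sample metadata and the Z-scoring state.
#'
#' @param values numeric matrix with feature ids as column names.
#' @param meta data frame with one row per matrix row (`slide_id`,
#'   `patient_id`, `site_id`, `cancer_type`).
#' @param z_scored whether columns are already Z-scores.
#' @param center,scale per-column normalization constants (when z-scored).
#' @return object of class `hif_matrix`.
#' @export
hif_matrix <- function(values, meta, z_scored = FALSE, center = NULL, scale = NULL) {
  stopifnot(is.matrix(values), nrow(values) == nrow(meta))
  structure(list(values = values, meta = meta, z_scored = z_scored,
                 center = center, scale = scale),
            class = "hif_matrix")
}

#' @export
print.hif_matrix <- function(x, ...) {
  cat(sprintf("<hif_matrix> %d sample(s) x %d feature(s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$z_scored) ", z-scored" else ""))
  invisible(x)
}

#' Aggregate a slide-level HIF matrix to patients
#'
#' Patients with multiple slides are represented by the single slide with the
#' largest CT+CAS area (the `area_mm2_ct_cas` feature); ties break to the
#' lexicographically smallest slide id. Aggregating an already patient-level
#' matrix is the identity.
#'
#' @param hm a slide-level `hif_matrix`.
#' @return a patient-level `hif_matrix` (rows named by patient id).
#' @export
aggregate_patients <- function(hm) {
  stopifnot(inherits(hm, "hif_matrix"))
  area <- hm$values[, "area_mm2_ct_cas"]
  ord <- order(hm$meta$patient_id, -area, hm$meta$slide_id)
  keep <- ord[!duplicated(hm$meta$patient_id[ord])]
  keep <- sort(keep)
  vals <- hm$values[keep, , drop = FALSE]
  meta <- hm$meta[keep, , drop = FALSE]
  rownames(vals) <- meta$patient_id
  rownames(meta) <- NULL
  hif_matrix(vals, meta, z_scored = hm$z_scored,
             center = hm$center, scale = hm$scale)
}

#' Z-score a HIF matrix
#'
#' Column-wise `(x - mean) / SD` over non-missing entries, using the
#' population SD (so Z-scoring twice is the identity). Constant columns map
#' to zero, and missing entries are imputed as 0 after scaling — i.e. at the
#' cohort mean — which keeps downstream penalized models defined.
#'
#' @param hm a `hif_matrix` with at least two rows.
#' @return a z-scored `hif_matrix` with no missing values.
#' @export
zscore_hifs <- function(hm) {
  stopifnot(inherits(hm, "hif_matrix"))
  if (nrow(hm$values) < 2) stop("z-scoring needs at least two rows")
  v <- hm$values
  ctr <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) return(0)
    sqrt(mean((col - mean(col))^2))
  })
  out <- sweep(v, 2, ctr, "-")
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sdv[nz], "/")
  out[, !nz] <- 0
  out[is.na(out)] <- 0
  hif_matrix(out, hm$meta, z_scored = TRUE, center = ctr, scale = sdv)
}

#' Cluster HIFs into correlated groups
#'
#' Agglomerative clustering of the features with complete linkage on the
#' correlation distance `1 - |Spearman rho|`, cut at `cutoff` (default 0.95),
#' so that within every cluster all pairwise absolute correlations are at
#' least `1 - cutoff`. Feature pairs with undefined correlation (constant
#' columns) are assigned distance 1.
#'
#' @param hm a `hif_matrix` with at least three rows.
#' @param cutoff dendrogram cut height.
#' @return object of class `hif_clusters`: a list with `assignment` (named
#'   integer vector feature -> cluster id), `n_clusters`, `cutoff`.
#' @export
cluster_hifs <- function(hm, cutoff = 0.95) {
  stopifnot(inherits(hm, "hif_matrix"))
  if (nrow(hm$values) < 3) stop("clustering needs at least three rows")
  rho <- suppressWarnings(stats::cor(hm$values, method = "spearman",
                                     use = "pairwise.complete.obs"))
  d <- 1 - abs(rho)
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  assignment <- stats::cutree(hc, h = cutoff)
  structure(list(assignment = assignment, n_clusters = max(assignment),
                 cutoff = cutoff),
            class = "hif_clusters")
}

#' @export
print.hif_clusters <- function(x, ...) {
  cat(sprintf("<hif_clusters> %d features in %d clusters (cutoff %.2f)\n",
              length(x$assignment), x$n_clusters, x$cutoff))
  invisible(x)
}
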