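#' Run one pipeline stage
#'
#' Thin orchestration over the package's functions, reading and writing
#' plain-text artifacts in a working directory:
#'
#' * `simulate` — generate a synthetic cohort; writes one PNG raster and cell
#'   CSV per slide, `metadata.csv`, `outcomes.csv` and `truth.json`.
#' * `extract` — read the slide set and write the slide-level `hifs_slide.csv`
#'   and the aggregated, z-scored patient-level `hifs.csv` plus
#'   `manifest.json`.
#' * `cluster` — cluster the HIFs of `hifs.csv`; writes `clusters.json`.
#' * `correlate` — associate HIFs and HIF clusters with each signature column
#'   of `signatures.csv` (keyed by patient_id); writes `associations.csv`.
#' * `predict` — GMM-binarize `outcomes.csv`, split by site, fit the nested
#'   CV sparse-group-lasso ensemble; writes `model.json`, `eval.json`,
#'   `betas.csv`.
#'
#' @param command one of `simulate`, `extract`, `cluster`, `correlate`,
#'   `predict`.
#' @param dir working directory for artifacts.
#' @param config a [hif_config()].
#' @param seed integer seed for the stage's randomness.
#' @param spec a [cohort_spec()] (simulate only; its `master_seed` is
#'   overridden by `seed`).
#' @return invisibly, the stage's primary result object.
#' @export
run_pipeline <- function(command = c("simulate", "extract", "cluster",
                                     "correlate", "predict"),
                         dir = ".", config = hif_config(), seed = 1,
                         spec = cohort_spec()) {
  command <- match.arg(command)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(command,
         simulate = pipeline_simulate(dir, config, seed, spec),
         extract = pipeline_extract(dir, config),
         cluster = pipeline_cluster(dir, config),
         correlate = pipeline_correlate(dir, config),
         predict = pipeline_predict(dir, config, seed))
}

pipeline_simulate <- function(dir, config, seed, spec) {
  spec$master_seed <- as.integer(seed)
  cohort <- generate_cohort(spec, config)
  meta <- lapply(cohort$slides, function(s) {
    write_slide_map(s, file.path(dir, paste0(s$slide_id, ".png")),
                    file.path(dir, paste0(s$slide_id, "_cells.csv")))
  })
  meta <- do.call(rbind, lapply(meta, as.data.frame))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(active_clusters = cohort$truth$active_clusters,
         noise_sd = cohort$truth$noise_sd,
         beta_true = as.list(cohort$truth$beta_true[cohort$truth$beta_true != 0])),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

pipeline_extract <- function(dir, config) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  slides <- lapply(seq_len(nrow(meta)), function(i) {
    load_slide_map(file.path(dir, paste0(meta$slide_id[i], ".png")),
                   file.path(dir, paste0(meta$slide_id[i], "_cells.csv")),
                   meta[i, ])
  })
  manifest <- hif_manifest(config)
  hm_slide <- extract_cohort(slides, manifest, config)
  hm_pat <- zscore_hifs(aggregate_patients(hm_slide))
  write.csv(data.frame(slide_id = rownames(hm_slide$values),
                       hm_slide$values, check.names = FALSE),
            file.path(dir, "hifs_slide.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = rownames(hm_pat$values),
                       hm_pat$values, check.names = FALSE),
            file.path(dir, "hifs.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(hm_pat)
}

read_hif_csv <- function(path, meta) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  m <- meta[match(df[[1]], meta$patient_id), , drop = FALSE]
  hif_matrix(vals, data.frame(slide_id = df[[1]], patient_id = df[[1]],
                              site_id = m$site_id, cancer_type = m$cancer_type,
                              stringsAsFactors = FALSE),
             z_scored = TRUE)
}

pipeline_cluster <- function(dir, config) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  hm <- read_hif_csv(file.path(dir, "hifs.csv"), meta)
  clusters <- cluster_hifs(hm, cutoff = config$cluster_cutoff)
  jsonlite::write_json(as.list(clusters$assignment),
                       file.path(dir, "clusters.json"), auto_unbox = TRUE)
  invisible(clusters)
}

pipeline_correlate <- function(dir, config) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  hm <- read_hif_csv(file.path(dir, "hifs.csv"), meta)
  assign_list <- jsonlite::read_json(file.path(dir, "clusters.json"))
  clusters <- list(assignment = setNames(unlist(assign_list), names(assign_list)),
                   n_clusters = max(unlist(assign_list)), cutoff = config$cluster_cutoff)
  sig <- read.csv(file.path(dir, "signatures.csv"), stringsAsFactors = FALSE)
  out <- list()
  for (col in setdiff(names(sig), "patient_id")) {
    v <- setNames(sig[[col]], sig$patient_id)
    per_hif <- spearman_assoc(hm, v)
    per_cluster <- cluster_assoc_summary(per_hif, clusters, hm)
    per_hif$level <- "hif"; per_hif$signature <- col
    per_cluster$level <- "cluster"; per_cluster$signature <- col
    out[[length(out) + 1]] <- per_hif
    out[[length(out) + 1]] <- per_cluster
  }
  res <- do.call(rbind, lapply(out, function(d) {
    data.frame(signature = d$signature, level = d$level,
               id = if ("feature_id" %in% names(d)) d$feature_id else d$cluster_id,
               rho = if ("rho" %in% names(d)) d$rho else d$median_abs_rho,
               p = if ("p" %in% names(d)) d$p else d$p_brown,
               q = if ("q" %in% names(d)) d$q else NA_real_,
               stringsAsFactors = FALSE)
  }))
  write.csv(res, file.path(dir, "associations.csv"), row.names = FALSE)
  invisible(res)
}

pipeline_predict <- function(dir, config, seed) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  hm <- read_hif_csv(file.path(dir, "hifs.csv"), meta)
  assign_list <- jsonlite::read_json(file.path(dir, "clusters.json"))
  groups <- unlist(assign_list)[colnames(hm$values)]
  outcomes <- read.csv(file.path(dir, "outcomes.csv"), stringsAsFactors = FALSE)
  y_cont <- setNames(outcomes$phenotype, outcomes$patient_id)[rownames(hm$values)]
  bin <- gmm_binarize(y_cont)
  split <- site_holdout_split(
    data.frame(patient_id = rownames(hm$values), site_id = hm$meta$site_id),
    frac_range = config$holdout_frac_range, seed = seed)
  tr <- rownames(hm$values) %in% split$train
  ens <- nested_cv_ensemble(hm$values[tr, , drop = FALSE], bin$labels[tr],
                            groups, seed = seed, config = config)
  probs <- predict(ens, hm$values[!tr, , drop = FALSE])
  ev <- evaluate_predictions(probs, bin$labels[!tr],
                             n_boot = config$n_bootstrap, seed = seed)
  jsonlite::write_json(
    list(lambda = ens$lambda, alpha = ens$alpha, seed = seed,
         intercepts = ens$intercepts,
         holdout_sites = split$holdout_sites,
         beta = as.list(ens$beta[ens$beta != 0])),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(ev, file.path(dir, "eval.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(data.frame(feature_id = names(ens$beta), beta = unname(ens$beta),
                       cluster_id = unname(groups)),
            file.path(dir, "betas.csv"), row.names = FALSE)
  invisible(list(ensemble = ens, evaluation = ev, split = split,
                 binarization = bin))
}
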