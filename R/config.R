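#' Analysis configuration
#'
#' Collects every tunable constant of the feature catalog and the modeling
#' stack in one record. Defaults are the published values where the method
#' states them (80 um proximity radius; Birch threshold 100 on micron
#' coordinates with branching factor 10; significant-component fraction 0.10;
#' HIF cluster cutoff 0.95; 3 outer x 5 inner cross-validation folds; 1000
#' bootstrap resamples and permutation iterations), and documented package
#' choices elsewhere (40 um CSI half-width, i.e. an 80 um total interface
#' band; gliding-box lacunarity at 32 px; perimeter smoothing sigma 1 px;
#' sparse-group-lasso mixing alpha 0.95 with a 30-point, 3-decade lambda
#' grid).
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `hif_config`.
#' @export
hif_config <- function(...) {
  cfg <- list(
    csi_halfwidth_um = 40,
    proximity_radius_um = 80,
    significant_fraction = 0.10,
    lacunarity_box_px = 32,
    perimeter_sigma_px = 1,
    birch_threshold_um = 100,
    birch_branching = 10,
    cluster_cutoff = 0.95,
    sgl_alpha = 0.95,
    lambda_grid_size = 30,
    lambda_decades = 3,
    n_outer_folds = 3,
    n_inner_folds = 5,
    n_bootstrap = 1000,
    n_permutations = 1000,
    holdout_frac_range = c(0.20, 0.30),
    pvalue_floor = 1e-30)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, override)
  for (fld in c("csi_halfwidth_um", "proximity_radius_um", "birch_threshold_um"))
    if (cfg[[fld]] <= 0) stop("config field `", fld, "` must be positive")
  if (cfg$significant_fraction <= 0 || cfg$significant_fraction > 1)
    stop("config field `significant_fraction` must lie in (0, 1]")
  structure(cfg, class = c("hif_config", "list"))
}
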