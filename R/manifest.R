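#' Enumerate the HIF catalog manifest
#'
#' Deterministically lists all 607 features with their category, cell class,
#' region, metric and aggregation scope, in the exact column order of the
#' extracted feature rows. Category totals are pinned to the published
#' catalog structure — count/density 56, cluster 180, proportion/proximity
#' 208, area/multiplicity 13, architecture 25, morphology 125; 163
#' tissue-derived and 444 cell-derived in total — and verified at build time;
#' any configuration edit that breaks a total is a hard error naming the
#' offending category.
#'
#' @param config a [hif_config()] (reserved for future catalog variants).
#' @return data frame of class `hif_manifest` with columns `feature_id`,
#'   `category`, `cell_class`, `region`, `metric`, `scope`.
#' @export
hif_manifest <- function(config = hif_config()) {
  if (!is.null(.manifest_cache$manifest)) return(.manifest_cache$manifest)
  rows <- list()
  add <- function(feature_id, category, cell_class = NA_character_,
                  region = NA_character_, metric = NA_character_,
                  scope = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      feature_id = feature_id, category = category, cell_class = cell_class,
      region = region, metric = metric, scope = scope,
      stringsAsFactors = FALSE)
  }

  # --- area & multiplicity (13), matching area_features_ctx order
  for (kind in c("ct", "cas", "ct_cas", "csi", "necrosis"))
    add(paste0("area_mm2_", kind), "area_multiplicity", region = kind, metric = "area_mm2")
  for (kind in c("ct", "cas", "ct_cas", "necrosis"))
    add(paste0("n_significant_", kind), "area_multiplicity", region = kind,
        metric = "n_significant")
  add("relative_area_cas_in_ct_cas", "area_multiplicity", region = "cas", metric = "relative_area")
  add("relative_area_ct_in_ct_cas", "area_multiplicity", region = "ct", metric = "relative_area")
  add("relative_area_necrosis_in_tumor_necrosis", "area_multiplicity",
      region = "necrosis", metric = "relative_area")
  add("relative_area_csi_in_ct_cas", "area_multiplicity", region = "csi", metric = "relative_area")

  # --- morphology (125), matching morphology_features_ctx order
  for (kind in MORPH_REGIONS) for (metric in MORPH_METRICS) for (scope in SCOPES)
    add(paste("morph", metric, scope, kind, sep = "_"), "morphology",
        region = kind, metric = metric, scope = scope)
  for (metric in CSI_MORPH_METRICS)
    add(paste("morph", metric, "largest_csi", sep = "_"), "morphology",
        region = "csi", metric = metric, scope = "largest")

  # --- architecture (25)
  for (kind in MORPH_REGIONS) for (metric in ARCH_METRICS) for (scope in SCOPES)
    add(paste("arch", metric, scope, kind, sep = "_"), "architecture",
        region = kind, metric = metric, scope = scope)
  add("arch_fractal_dimension_interface_csi", "architecture", region = "csi",
      metric = "fractal_dimension", scope = "interface")

  # --- count & density (56)
  for (cls in CELL_CLASSES) for (kind in CELL_REGIONS_CD) for (metric in c("count", "density"))
    add(paste("cd", cls, metric, kind, sep = "_"), "count_density",
        cell_class = cls, region = kind, metric = metric)
  for (kind in c("ct", "cas", "ct_cas")) for (metric in c("count", "density"))
    add(paste("cd_total", metric, kind, sep = "_"), "count_density",
        cell_class = "all", region = kind, metric = metric)

  # --- proportion & proximity (208)
  for (cls in CELL_CLASSES) for (kind in CELL_REGIONS_CLUST)
    add(paste("pp_prop", cls, kind, sep = "_"), "proportion_proximity",
        cell_class = cls, region = kind, metric = "proportion")
  for (a in CELL_CLASSES) for (b in setdiff(CELL_CLASSES, a))
    for (kind in c("ct_cas", "csi")) for (metric in c("count", "prop"))
      add(paste("pp_prox", a, b, metric, kind, sep = "_"), "proportion_proximity",
          cell_class = paste(a, b, sep = ":"), region = kind,
          metric = paste0("proximity_", metric))
  for (cls in CELL_CLASSES)
    for (pair in list(c("ct", "cas"), c("ct", "ct_cas"), c("cas", "ct_cas")))
      add(paste("pp_logratio_density", cls, pair[1], "vs", pair[2], sep = "_"),
          "proportion_proximity", cell_class = cls,
          region = paste(pair, collapse = ":"), metric = "density_logratio")
  for (cls in CELL_CLASSES) for (metric in c("count", "density", "prop"))
    add(paste("pp_iface", cls, metric, sep = "_"), "proportion_proximity",
        cell_class = cls, region = "csi", metric = paste0("iface_", metric))
  pairs <- utils::combn(CELL_CLASSES, 2)
  for (p in seq_len(ncol(pairs))) for (kind in CELL_REGIONS_CLUST)
    add(paste("pp_pairprop", pairs[1, p], pairs[2, p], kind, sep = "_"),
        "proportion_proximity", cell_class = paste(pairs[, p], collapse = ":"),
        region = kind, metric = "pair_proportion")
  for (p in seq_len(ncol(pairs)))
    add(paste("pp_iface_pairprop", pairs[1, p], pairs[2, p], sep = "_"),
        "proportion_proximity", cell_class = paste(pairs[, p], collapse = ":"),
        region = "csi", metric = "iface_pair_proportion")
  for (p in seq_len(ncol(pairs)))
    add(paste("pp_iface_logratio_density", pairs[1, p], pairs[2, p], sep = "_"),
        "proportion_proximity", cell_class = paste(pairs[, p], collapse = ":"),
        region = "csi", metric = "iface_density_logratio")
  for (cls in CELL_CLASSES) for (metric in c("count", "prop"))
    add(paste("pp_far", cls, metric, sep = "_"), "proportion_proximity",
        cell_class = cls, region = "ct_cas", metric = paste0("far_", metric))
  for (cls in CELL_CLASSES)
    add(paste("pp_csi_logratio_density", cls, sep = "_"), "proportion_proximity",
        cell_class = cls, region = "csi", metric = "csi_density_logratio")
  for (metric in c("count", "density", "prop"))
    add(paste("pp_iface_total", metric, sep = "_"), "proportion_proximity",
        cell_class = "all", region = "csi", metric = paste0("iface_total_", metric))

  # --- cluster (180)
  for (cls in CELL_CLASSES) for (kind in CELL_REGIONS_CLUST) for (metric in CLUSTER_METRICS)
    add(paste("clust", cls, metric, kind, sep = "_"), "cluster",
        cell_class = cls, region = kind, metric = metric)

  manifest <- do.call(rbind, rows)
  expected <- c(area_multiplicity = 13L, morphology = 125L, architecture = 25L,
                count_density = 56L, proportion_proximity = 208L, cluster = 180L)
  got <- table(factor(manifest$category, levels = names(expected)))
  for (cat in names(expected)) {
    if (got[[cat]] != expected[[cat]])
      stop(sprintf("catalog category '%s' has %d features, expected %d",
                   cat, got[[cat]], expected[[cat]]))
  }
  if (nrow(manifest) != 607L) stop("catalog does not total 607 features")
  if (anyDuplicated(manifest$feature_id)) stop("duplicate feature ids in catalog")
  class(manifest) <- c("hif_manifest", "data.frame")
  .manifest_cache$manifest <- manifest
  manifest
}

# the catalog is a fixed enumeration; build it once per session
.manifest_cache <- new.env(parent = emptyenv())

# categories computed from the tissue raster alone
TISSUE_CATEGORIES <- c("area_multiplicity", "morphology", "architecture")
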