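# Shared per-slide geometry: region masks, component sets, interface, and
# per-cell region membership. Built once per slide and threaded through every
# feature family.
slide_context <- function(slide, config = hif_config()) {
  regions <- list()
  for (kind in REGION_KINDS)
    regions[[kind]] <- region_mask(slide, kind,
                                   csi_halfwidth_um = config$csi_halfwidth_um)
  comps <- lapply(regions, connected_components)
  sig <- lapply(comps, significant_components,
                fraction = config$significant_fraction)
  iface <- csi_interface(slide)
  # 80 um interface band (proximity radius), for interface cell features
  band <- if (config$proximity_radius_um == config$csi_halfwidth_um) {
    regions$csi
  } else {
    region_mask(slide, "csi", csi_halfwidth_um = config$proximity_radius_um)
  }
  cells <- slide$cells
  in_region <- lapply(regions, function(rm) cells_in_mask(cells, rm$mask, slide$mpp))
  in_band <- cells_in_mask(cells, band$mask, slide$mpp)
  iface_dist <- if (nrow(cells) > 0 && length(iface$edge_x) > 0) {
    cpp_nearest_index(cells$x_um, cells$y_um, iface$edge_x, iface$edge_y)$distance
  } else {
    rep(Inf, nrow(cells))
  }
  list(slide = slide, config = config, regions = regions, comps = comps,
       sig = sig, iface = iface, band = band, in_region = in_region,
       in_band = in_band, iface_dist = iface_dist, cache = new.env())
}

#' Tissue area and multiplicity features (13 HIFs)
#'
#' Absolute areas in mm^2 of cancer tissue (CT), cancer-associated stroma
#' (CAS), their union, the cancer-stroma interface band (CSI) and necrosis;
#' the number of significant connected components of CT, CAS, CT+CAS and
#' necrosis; and four relative areas. Ratios with a zero denominator are
#' returned as `NA`.
#'
#' @param slide a [slide_map()].
#' @param config a [hif_config()].
#' @return named numeric vector of length 13.
#' @export
area_multiplicity_features <- function(slide, config = hif_config()) {
  ctx <- slide_context(slide, config)
  area_features_ctx(ctx)
}

area_features_ctx <- function(ctx) {
  a <- vapply(ctx$regions, function(r) r$area_mm2, 1.0)
  nsig <- vapply(ctx$sig[c("ct", "cas", "ct_cas", "necrosis")],
                 function(s) nrow(s$components), 1L)
  safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(area_mm2_ct = a[["ct"]],
    area_mm2_cas = a[["cas"]],
    area_mm2_ct_cas = a[["ct_cas"]],
    area_mm2_csi = a[["csi"]],
    area_mm2_necrosis = a[["necrosis"]],
    n_significant_ct = nsig[["ct"]],
    n_significant_cas = nsig[["cas"]],
    n_significant_ct_cas = nsig[["ct_cas"]],
    n_significant_necrosis = nsig[["necrosis"]],
    relative_area_cas_in_ct_cas = safe_ratio(a[["cas"]], a[["ct_cas"]]),
    relative_area_ct_in_ct_cas = safe_ratio(a[["ct"]], a[["ct_cas"]]),
    relative_area_necrosis_in_tumor_necrosis =
      safe_ratio(a[["necrosis"]], a[["ct_cas"]] + a[["necrosis"]]),
    relative_area_csi_in_ct_cas = safe_ratio(a[["csi"]], a[["ct_cas"]]))
}

MORPH_METRICS <- c("major_axis_um", "minor_axis_um", "convex_area_mm2",
                   "filled_area_mm2", "euler_number", "lacunarity",
                   "eccentricity", "perimeter_um", "shape_roughness",
                   "extent_bbox")
ARCH_METRICS <- c("fractal_dimension", "solidity")
SCOPES <- c("largest", "sig_mean", "sig_sd")
MORPH_REGIONS <- c("ct", "cas", "ct_cas", "necrosis")
CSI_MORPH_METRICS <- c("major_axis_um", "minor_axis_um", "eccentricity",
                       "perimeter_um", "shape_roughness")

# per-significant-component metric table for one region (cached in the
# context: morphology and architecture features share it)
region_component_metrics <- function(ctx, kind) {
  if (!is.null(ctx$cache) && !is.null(ctx$cache[[kind]]))
    return(ctx$cache[[kind]])
  sig <- ctx$sig[[kind]]
  if (nrow(sig$components) == 0) return(NULL)
  rows <- lapply(sig$components$component_id, function(id) {
    component_metrics(component_submask(sig, id), ctx$slide$mpp,
                      lacunarity_box = ctx$config$lacunarity_box_px)
  })
  out <- do.call(rbind, rows)
  if (!is.null(ctx$cache)) ctx$cache[[kind]] <- out
  out
}

scope_aggregate <- function(metric_table, metric) {
  vals <- metric_table[, metric]
  # population SD: a single significant component has zero heterogeneity
  c(largest = vals[1], sig_mean = mean(vals, na.rm = TRUE),
    sig_sd = if (all(is.na(vals))) NA_real_ else {
      v <- vals[!is.na(vals)]
      sqrt(mean((v - mean(v))^2))
    })
}

#' Tissue morphology features (125 HIFs)
#'
#' Ten shape metrics per region component (see [component_metrics()]),
#' aggregated over three scopes (largest component; mean and SD across
#' significant components) for CT, CAS, CT+CAS and necrosis, plus five
#' metrics of the largest CSI-band component. Empty regions yield `NA`.
#'
#' @inheritParams area_multiplicity_features
#' @return named numeric vector of length 125.
#' @export
morphology_features <- function(slide, config = hif_config()) {
  morphology_features_ctx(slide_context(slide, config))
}

morphology_features_ctx <- function(ctx) {
  out <- numeric(0)
  for (kind in MORPH_REGIONS) {
    mt <- region_component_metrics(ctx, kind)
    for (metric in MORPH_METRICS) {
      vals <- if (is.null(mt)) {
        c(largest = NA_real_, sig_mean = NA_real_, sig_sd = NA_real_)
      } else {
        scope_aggregate(mt, metric)
      }
      names(vals) <- paste("morph", metric, SCOPES, kind, sep = "_")
      out <- c(out, vals)
    }
  }
  csi_mt <- region_component_metrics(ctx, "csi")
  csi_vals <- if (is.null(csi_mt)) {
    rep(NA_real_, length(CSI_MORPH_METRICS))
  } else {
    csi_mt[1, CSI_MORPH_METRICS]
  }
  names(csi_vals) <- paste("morph", CSI_MORPH_METRICS, "largest_csi", sep = "_")
  c(out, csi_vals)
}

#' Tissue architecture features (25 HIFs)
#'
#' Fractal dimension (box counting over component boundary pixels) and
#' solidity (component area over convex hull area) per region and scope, plus
#' the fractal dimension of the CT|CAS interface curve itself.
#'
#' @inheritParams area_multiplicity_features
#' @return named numeric vector of length 25.
#' @export
architecture_features <- function(slide, config = hif_config()) {
  architecture_features_ctx(slide_context(slide, config))
}

architecture_features_ctx <- function(ctx) {
  out <- numeric(0)
  for (kind in MORPH_REGIONS) {
    mt <- region_component_metrics(ctx, kind)
    for (metric in ARCH_METRICS) {
      vals <- if (is.null(mt)) {
        c(largest = NA_real_, sig_mean = NA_real_, sig_sd = NA_real_)
      } else {
        scope_aggregate(mt, metric)
      }
      names(vals) <- paste("arch", metric, SCOPES, kind, sep = "_")
      out <- c(out, vals)
    }
  }
  iface <- ctx$iface
  ifd <- if (length(iface$edge_x) >= 2) {
    fractal_dimension(iface$edge_x / ctx$slide$mpp, iface$edge_y / ctx$slide$mpp)
  } else {
    NA_real_
  }
  c(out, arch_fractal_dimension_interface_csi = ifd)
}
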