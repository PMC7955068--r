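CELL_REGIONS_CD <- c("ct", "cas", "ct_cas", "csi", "necrosis")
CELL_REGIONS_CLUST <- c("ct", "cas", "ct_cas", "csi")

#' Cell count and density features (56 HIFs)
#'
#' Counts and densities (count per mm^2 of region area) of the five cell
#' classes in CT, CAS, CT+CAS, CSI and necrosis, plus total-cell counts and
#' densities in CT, CAS and CT+CAS. Densities over an empty region are `NA`.
#'
#' @inheritParams area_multiplicity_features
#' @return named numeric vector of length 56.
#' @export
count_density_features <- function(slide, config = hif_config()) {
  count_density_ctx(slide_context(slide, config))
}

count_density_ctx <- function(ctx) {
  cells <- ctx$slide$cells
  out <- numeric(0)
  for (cls in CELL_CLASSES) {
    is_cls <- cells$cell_class == cls
    for (kind in CELL_REGIONS_CD) {
      cnt <- sum(is_cls & ctx$in_region[[kind]])
      area <- ctx$regions[[kind]]$area_mm2
      v <- c(cnt, if (area > 0) cnt / area else NA_real_)
      names(v) <- paste("cd", cls, c("count", "density"), kind, sep = "_")
      out <- c(out, v)
    }
  }
  for (kind in c("ct", "cas", "ct_cas")) {
    cnt <- sum(ctx$in_region[[kind]])
    area <- ctx$regions[[kind]]$area_mm2
    v <- c(cnt, if (area > 0) cnt / area else NA_real_)
    names(v) <- paste("cd_total", c("count", "density"), kind, sep = "_")
    out <- c(out, v)
  }
  out
}

#' Proximity pair count
#'
#' Number of class-a cells whose nearest class-b cell lies within `radius`
#' (Euclidean, microns). Each a-cell is counted at most once. Computed with a
#' spatial grid index, contractually identical to the all-pairs search.
#'
#' @param ax,ay coordinates of the a cells (microns).
#' @param bx,by coordinates of the b cells.
#' @param radius proximity radius in microns (default 80).
#' @return integer count.
#' @export
proximity_pair_count <- function(ax, ay, bx, by, radius = 80) {
  stopifnot(radius > 0)
  if (length(ax) == 0 || length(bx) == 0) return(0L)
  sum(cpp_has_neighbor(as.numeric(ax), as.numeric(ay),
                       as.numeric(bx), as.numeric(by), radius))
}

#' Cell proportion and proximity features (208 HIFs)
#'
#' Six documented families (see the catalog manifest for every entry):
#' per-region class proportions; ordered-pair 80 um proximity counts and
#' proportions in CT+CAS and in the CSI band; cross-region density log-ratios;
#' class counts/densities/proportions within 80 um of the interface curve;
#' unordered pairwise proportional counts `a/(a+b)` per region; and
#' interface-anchored pairwise contrasts. Zero denominators yield `NA`.
#'
#' @inheritParams area_multiplicity_features
#' @return named numeric vector of length 208.
#' @export
proportion_proximity_features <- function(slide, config = hif_config()) {
  proportion_proximity_ctx(slide_context(slide, config))
}

proportion_proximity_ctx <- function(ctx) {
  cells <- ctx$slide$cells
  radius <- ctx$config$proximity_radius_um
  is_cls <- lapply(setNames(CELL_CLASSES, CELL_CLASSES),
                   function(cl) cells$cell_class == cl)
  near_iface <- is.finite(ctx$iface_dist) & ctx$iface_dist <= radius &
    ctx$in_region$ct_cas
  band_area <- ctx$band$area_mm2
  csi_area <- ctx$regions$csi$area_mm2
  safe_div <- function(num, den) if (length(den) && !is.na(den) && den > 0) num / den else NA_real_
  out <- numeric(0)

  # (i) class proportions per region: 5 x 4 = 20
  for (cls in CELL_CLASSES) {
    for (kind in CELL_REGIONS_CLUST) {
      tot <- sum(ctx$in_region[[kind]])
      v <- safe_div(sum(is_cls[[cls]] & ctx$in_region[[kind]]), tot)
      out <- c(out, setNames(v, paste("pp_prop", cls, kind, sep = "_")))
    }
  }

  # (ii) ordered-pair proximity count and proportion-of-a, in CT+CAS and CSI: 80
  for (a in CELL_CLASSES) for (b in setdiff(CELL_CLASSES, a)) {
    for (kind in c("ct_cas", "csi")) {
      sel <- ctx$in_region[[kind]]
      asel <- is_cls[[a]] & sel; bsel <- is_cls[[b]] & sel
      cnt <- proximity_pair_count(cells$x_um[asel], cells$y_um[asel],
                                  cells$x_um[bsel], cells$y_um[bsel], radius)
      v <- c(cnt, safe_div(cnt, sum(asel)))
      names(v) <- paste("pp_prox", a, b, c("count", "prop"), kind, sep = "_")
      out <- c(out, v)
    }
  }

  # (iii) cross-region density log-ratios: 5 x 3 = 15
  dens <- function(cls, kind) {
    area <- ctx$regions[[kind]]$area_mm2
    if (area > 0) sum(is_cls[[cls]] & ctx$in_region[[kind]]) / area else NA_real_
  }
  for (cls in CELL_CLASSES) {
    for (pair in list(c("ct", "cas"), c("ct", "ct_cas"), c("cas", "ct_cas"))) {
      d1 <- dens(cls, pair[1]); d2 <- dens(cls, pair[2])
      v <- if (is.na(d1) || is.na(d2) || d1 <= 0 || d2 <= 0) NA_real_ else log2(d1 / d2)
      out <- c(out, setNames(v, paste("pp_logratio_density", cls, pair[1],
                                      "vs", pair[2], sep = "_")))
    }
  }

  # (iv) class features within 80 um of the interface curve: 5 x 3 = 15
  for (cls in CELL_CLASSES) {
    cnt <- sum(is_cls[[cls]] & near_iface)
    v <- c(cnt, safe_div(cnt, band_area),
           safe_div(cnt, sum(is_cls[[cls]] & ctx$in_region$ct_cas)))
    names(v) <- paste("pp_iface", cls, c("count", "density", "prop"), sep = "_")
    out <- c(out, v)
  }

  # (v) unordered pairwise proportional counts a/(a+b) per region: 10 x 4 = 40
  pairs <- utils::combn(CELL_CLASSES, 2)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    for (kind in CELL_REGIONS_CLUST) {
      na_ <- sum(is_cls[[a]] & ctx$in_region[[kind]])
      nb_ <- sum(is_cls[[b]] & ctx$in_region[[kind]])
      v <- safe_div(na_, na_ + nb_)
      out <- c(out, setNames(v, paste("pp_pairprop", a, b, kind, sep = "_")))
    }
  }

  # (vi) interface-anchored contrasts: 10 + 10 + 18 = 38
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    na_ <- sum(is_cls[[a]] & near_iface)
    nb_ <- sum(is_cls[[b]] & near_iface)
    out <- c(out, setNames(safe_div(na_, na_ + nb_),
                           paste("pp_iface_pairprop", a, b, sep = "_")))
  }
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    da <- safe_div(sum(is_cls[[a]] & near_iface), band_area)
    db <- safe_div(sum(is_cls[[b]] & near_iface), band_area)
    v <- if (is.na(da) || is.na(db) || da <= 0 || db <= 0) NA_real_ else log2(da / db)
    out <- c(out, setNames(v, paste("pp_iface_logratio_density", a, b, sep = "_")))
  }
  for (cls in CELL_CLASSES) {
    far_cnt <- sum(is_cls[[cls]] & ctx$in_region$ct_cas & !near_iface)
    tot <- sum(is_cls[[cls]] & ctx$in_region$ct_cas)
    v <- c(far_cnt, safe_div(far_cnt, tot))
    names(v) <- paste("pp_far", cls, c("count", "prop"), sep = "_")
    out <- c(out, v)
  }
  for (cls in CELL_CLASSES) {
    d_csi <- safe_div(sum(is_cls[[cls]] & ctx$in_region$csi), csi_area)
    d_tum <- safe_div(sum(is_cls[[cls]] & ctx$in_region$ct_cas),
                      ctx$regions$ct_cas$area_mm2)
    v <- if (is.na(d_csi) || is.na(d_tum) || d_csi <= 0 || d_tum <= 0)
      NA_real_ else log2(d_csi / d_tum)
    out <- c(out, setNames(v, paste("pp_csi_logratio_density", cls, sep = "_")))
  }
  tot_near <- sum(near_iface)
  out <- c(out,
           pp_iface_total_count = tot_near,
           pp_iface_total_density = safe_div(tot_near, band_area),
           pp_iface_total_prop = safe_div(tot_near, sum(ctx$in_region$ct_cas)))
  out
}

CLUSTER_METRICS <- c("n_clusters", "size_mean", "size_sd", "dispersion_mean",
                     "dispersion_sd", "extent_mean", "extent_sd", "ball_hall",
                     "calinski_harabasz")

#' Birch spatial-cluster features (180 HIFs)
#'
#' For each cell class in CT, CAS, CT+CAS and CSI: number of Birch clusters,
#' cluster size mean/SD, within-cluster dispersion (mean member-exemplar
#' distance) mean/SD, cluster extent (max member-exemplar distance) mean/SD,
#' and the Ball-Hall and Calinski-Harabasz indices. Regions holding fewer
#' than two cells of a class report `NA` beyond the cluster count and size.
#'
#' @inheritParams area_multiplicity_features
#' @return named numeric vector of length 180.
#' @export
cluster_features <- function(slide, config = hif_config()) {
  cluster_features_ctx(slide_context(slide, config))
}

cluster_features_ctx <- function(ctx) {
  cells <- ctx$slide$cells
  out <- numeric(0)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (cls in CELL_CLASSES) {
    is_cls <- cells$cell_class == cls
    for (kind in CELL_REGIONS_CLUST) {
      sel <- is_cls & ctx$in_region[[kind]]
      n <- sum(sel)
      vals <- if (n == 0) {
        rep(NA_real_, 9)
      } else if (n == 1) {
        c(1, 1, 0, rep(NA_real_, 6))
      } else {
        cl <- birch_clusters(cells$x_um[sel], cells$y_um[sel],
                             threshold = ctx$config$birch_threshold_um,
                             branching = ctx$config$birch_branching)
        idx <- cluster_indices(cells$x_um[sel], cells$y_um[sel], cl$assignment)
        c(cl$K, mean(cl$size), pop_sd(cl$size),
          mean(cl$dispersion), pop_sd(cl$dispersion),
          mean(cl$extent), pop_sd(cl$extent),
          idx$ball_hall, idx$calinski_harabasz)
      }
      names(vals) <- paste("clust", cls, CLUSTER_METRICS, kind, sep = "_")
      out <- c(out, vals)
    }
  }
  out
}
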