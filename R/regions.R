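#' Derive an analysis region mask from a slide map
#'
#' Five region kinds are supported: `ct`, `cas` and `necrosis` are direct
#' code-equality masks; `ct_cas` is the elementwise union of CT and CAS (the
#' "tumor region"); `csi` is the cancer-stroma interface band, defined as all
#' CT or CAS pixels whose center lies within `csi_halfwidth_um` (Euclidean
#' distance in microns) of a pixel edge shared between a CT pixel and a CAS
#' pixel.
#'
#' @param slide a [slide_map()].
#' @param kind one of `"ct"`, `"cas"`, `"ct_cas"`, `"necrosis"`, `"csi"`.
#' @param csi_halfwidth_um half-width of the interface band in microns
#'   (default 40, i.e. an 80 um total band matching the proximity radius used
#'   by the cell features).
#' @return an object of class `region_mask`: a list with `kind`, logical
#'   `mask`, `mpp` and `area_mm2`.
#' @export
region_mask <- function(slide, kind, csi_halfwidth_um = 40) {
  kind <- match.arg(kind, REGION_KINDS)
  r <- slide$raster
  mask <- switch(kind,
    ct = r == TISSUE_CODES[["ct"]],
    cas = r == TISSUE_CODES[["cas"]],
    ct_cas = r == TISSUE_CODES[["ct"]] | r == TISSUE_CODES[["cas"]],
    necrosis = r == TISSUE_CODES[["necrosis"]],
    csi = csi_band_mask(slide, csi_halfwidth_um))
  new_region_mask(kind, mask, slide$mpp)
}

new_region_mask <- function(kind, mask, mpp) {
  structure(list(kind = kind, mask = mask, mpp = mpp,
                 area_mm2 = sum(mask) * (mpp / 1000)^2),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %d px, %.4f mm^2 @ %g um/px\n",
              x$kind, sum(x$mask), x$area_mm2, x$mpp))
  invisible(x)
}

#' Cancer-stroma interface geometry
#'
#' Locates every pixel edge shared between a CT pixel and a CAS pixel
#' (4-adjacency) and returns the edge midpoints in micron coordinates together
#' with the interface pixel set (the CT and CAS pixels incident to a shared
#' edge). The midpoints are the geometric anchor for the CSI band, for
#' cell-to-interface distances, and for the interface fractal dimension.
#'
#' @param slide a [slide_map()].
#' @return list with `edge_x`, `edge_y` (microns), `edge_i`, `edge_j`
#'   (1-based indices on the doubled grid), and `pixels` (logical matrix).
#' @export
csi_interface <- function(slide) {
  r <- slide$raster
  mpp <- slide$mpp
  nr <- nrow(r); nc <- ncol(r)
  ct <- r == TISSUE_CODES[["ct"]]
  cas <- r == TISSUE_CODES[["cas"]]
  pixels <- matrix(FALSE, nr, nc)
  # horizontal neighbors (r,c) | (r,c+1)
  hpair <- (ct[, -nc] & cas[, -1]) | (cas[, -nc] & ct[, -1])
  hidx <- which(hpair, arr.ind = TRUE) # row, left col
  # vertical neighbors (r,c) | (r+1,c)
  vpair <- (ct[-nr, ] & cas[-1, ]) | (cas[-nr, ] & ct[-1, ])
  vidx <- which(vpair, arr.ind = TRUE) # top row, col
  if (nrow(hidx)) {
    pixels[cbind(hidx[, 1], hidx[, 2])] <- TRUE
    pixels[cbind(hidx[, 1], hidx[, 2] + 1L)] <- TRUE
  }
  if (nrow(vidx)) {
    pixels[cbind(vidx[, 1], vidx[, 2])] <- TRUE
    pixels[cbind(vidx[, 1] + 1L, vidx[, 2])] <- TRUE
  }
  # midpoint of a vertical shared edge between horizontal neighbors (r, c),
  # (r, c+1): x = c*mpp, y = (r - 0.5)*mpp; doubled-grid index (2r, 2c+1)
  edge_x <- c(hidx[, 2] * mpp, (vidx[, 2] - 0.5) * mpp)
  edge_y <- c((hidx[, 1] - 0.5) * mpp, vidx[, 1] * mpp)
  edge_i <- c(2L * hidx[, 1], 2L * vidx[, 1] + 1L)
  edge_j <- c(2L * hidx[, 2] + 1L, 2L * vidx[, 2])
  list(edge_x = edge_x, edge_y = edge_y, edge_i = edge_i, edge_j = edge_j,
       pixels = pixels)
}

# CSI band: CT|CAS pixels with center within halfwidth_um of a shared CT|CAS
# pixel edge. Distances come from an exact Euclidean distance transform on a
# 2x-resolution grid, where both pixel centers and edge midpoints fall on
# integer positions.
csi_band_mask <- function(slide, halfwidth_um) {
  r <- slide$raster
  nr <- nrow(r); nc <- ncol(r)
  iface <- csi_interface(slide)
  union_mask <- r == TISSUE_CODES[["ct"]] | r == TISSUE_CODES[["cas"]]
  if (length(iface$edge_x) == 0) return(matrix(FALSE, nr, nc))
  dbl <- matrix(1, 2L * nr + 1L, 2L * nc + 1L)
  dbl[cbind(iface$edge_i, iface$edge_j)] <- 0
  dist_half_px <- EBImage::distmap(dbl, metric = "euclidean")
  centers <- dist_half_px[cbind(rep(2L * seq_len(nr), times = nc),
                                rep(2L * seq_len(nc), each = nr))]
  dist_um <- matrix(centers, nr, nc) / 2 * slide$mpp
  union_mask & dist_um <= halfwidth_um
}

#' Connected components of a region mask (eight-connectivity)
#'
#' Components are labeled at the pixel level with eight-connectivity and
#' sorted by descending pixel count (ties keep scan order).
#'
#' @param region a [region_mask()] or a logical matrix (then `mpp` is used).
#' @param mpp microns per pixel, when `region` is a bare matrix.
#' @return object of class `component_set`: `labels` (integer matrix, 0 =
#'   background, components numbered 1..K by descending size), `components`
#'   (data frame with `component_id`, `pixel_count`, bounding box), `mpp`.
#' @export
connected_components <- function(region, mpp = NULL) {
  if (inherits(region, "region_mask")) {
    mask <- region$mask
    mpp <- region$mpp
  } else {
    mask <- region
    if (is.null(mpp)) stop("`mpp` required when passing a bare mask")
  }
  lab <- cpp_label(mask, connectivity = 8L)
  k <- max(lab)
  if (k == 0) {
    comps <- data.frame(component_id = integer(0), pixel_count = integer(0),
                        rmin = integer(0), rmax = integer(0),
                        cmin = integer(0), cmax = integer(0))
    return(structure(list(labels = lab, components = comps, mpp = mpp),
                     class = "component_set"))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  comps <- data.frame(
    component_id = seq_len(k),
    pixel_count = sizes[ord],
    rmin = vapply(split(idx[, 1], labv), min, 1L),
    rmax = vapply(split(idx[, 1], labv), max, 1L),
    cmin = vapply(split(idx[, 2], labv), min, 1L),
    cmax = vapply(split(idx[, 2], labv), max, 1L))
  rownames(comps) <- NULL
  structure(list(labels = lab, components = comps, mpp = mpp),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s), %d foreground px\n",
              nrow(x$components), sum(x$components$pixel_count)))
  invisible(x)
}

#' Keep the significant connected components
#'
#' A component is significant when its pixel count is at least `fraction`
#' times the largest component's pixel count; the largest component is always
#' retained.
#'
#' @param comps a [connected_components()] result.
#' @param fraction size threshold relative to the largest component
#'   (default 0.10).
#' @return a `component_set` restricted to the significant components
#'   (labels of dropped components are zeroed; ids are preserved).
#' @export
significant_components <- function(comps, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(comps$components) == 0) return(comps)
  cutoff <- fraction * comps$components$pixel_count[1]
  keep <- comps$components$pixel_count >= cutoff
  keep[1] <- TRUE
  dropped <- comps$components$component_id[!keep]
  lab <- comps$labels
  if (length(dropped)) lab[lab %in% dropped] <- 0L
  structure(list(labels = lab, components = comps$components[keep, , drop = FALSE],
                 mpp = comps$mpp),
            class = "component_set")
}
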