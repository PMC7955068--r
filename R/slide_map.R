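#' Slide map: tissue raster plus cell point table
#'
#' The central per-slide container: a dense tissue-type label raster (integer
#' codes 0 = background/normal tissue, 1 = cancer tissue (CT), 2 =
#' cancer-associated stroma (CAS), 3 = necrosis) at a stated resolution in
#' microns per pixel, together with a table of classified cell centroids in
#' micron coordinates and the sample metadata needed downstream (patient,
#' tissue source site, cancer type).
#'
#' Coordinates are continuous microns with the origin at the raster's top-left
#' corner; pixel `(r, c)` (1-based) covers the half-open square
#' `[(c-1)*mpp, c*mpp) x [(r-1)*mpp, r*mpp)`. A cell belongs to a region iff
#' its containing pixel does.
#'
#' @param raster integer matrix of tissue codes in `{0, 1, 2, 3}`.
#' @param cells data frame with columns `x_um`, `y_um`, `cell_class`
#'   (`lymphocyte`, `plasma`, `fibroblast`, `macrophage`, `cancer`). May have
#'   zero rows.
#' @param slide_id,patient_id,site_id,cancer_type sample metadata strings.
#' @param mpp microns per pixel of the tissue raster (default 4).
#' @return an object of class `slide_map`.
#' @export
slide_map <- function(raster, cells = empty_cell_table(), slide_id = "slide",
                      patient_id = slide_id, site_id = "site",
                      cancer_type = "NA", mpp = 4) {
  if (!is.matrix(raster)) stop("`raster` must be a matrix")
  storage.mode(raster) <- "integer"
  bad <- setdiff(unique(as.vector(raster)), unname(TISSUE_CODES))
  if (length(bad)) stop("unknown tissue code(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(mpp) || length(mpp) != 1 || mpp <= 0) stop("`mpp` must be a positive scalar")
  cells <- validate_cells(cells, raster, mpp)
  structure(
    list(slide_id = as.character(slide_id), patient_id = as.character(patient_id),
         site_id = as.character(site_id), cancer_type = as.character(cancer_type),
         raster = raster, mpp = mpp, cells = cells),
    class = "slide_map")
}

#' @export
print.slide_map <- function(x, ...) {
  cat(sprintf("<slide_map> %s (patient %s, site %s, %s)\n",
              x$slide_id, x$patient_id, x$site_id, x$cancer_type))
  cat(sprintf("  raster %d x %d px @ %g um/px; %d cells\n",
              nrow(x$raster), ncol(x$raster), x$mpp, nrow(x$cells)))
  invisible(x)
}

#' @rdname slide_map
#' @export
empty_cell_table <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0),
             cell_class = character(0), stringsAsFactors = FALSE)
}

validate_cells <- function(cells, raster, mpp) {
  need <- c("x_um", "y_um", "cell_class")
  if (!is.data.frame(cells) || !all(need %in% names(cells)))
    stop("cell table must have columns x_um, y_um, cell_class")
  cells <- cells[need]
  cells$cell_class <- as.character(cells$cell_class)
  if (nrow(cells) == 0) return(cells)
  bad <- which(!cells$cell_class %in% CELL_CLASSES)
  if (length(bad))
    stop(sprintf("unknown cell class '%s' at cell table row %d",
                 cells$cell_class[bad[1]], bad[1]))
  w_um <- ncol(raster) * mpp
  h_um <- nrow(raster) * mpp
  out <- which(cells$x_um < 0 | cells$x_um >= w_um |
               cells$y_um < 0 | cells$y_um >= h_um | !is.finite(cells$x_um) |
               !is.finite(cells$y_um))
  if (length(out))
    stop(sprintf("cell at row %d (%.2f, %.2f) lies outside the raster extent %g x %g um",
                 out[1], cells$x_um[out[1]], cells$y_um[out[1]], w_um, h_um))
  rownames(cells) <- NULL
  cells
}

#' Read a slide map from disk
#'
#' The raster is a single-channel 8-bit PNG whose pixel values are the tissue
#' codes 0-3; the cell table is a CSV with header `x_um,y_um,cell_class`. The
#' resolution and identifiers travel in a metadata record (one row of the
#' cohort metadata CSV: `slide_id,patient_id,site_id,cancer_type,tissue_mpp`),
#' not in the image header.
#'
#' @param raster_path path to the PNG label raster.
#' @param cells_path path to the cell CSV.
#' @param meta list or one-row data frame with `slide_id`, `patient_id`,
#'   `site_id`, `cancer_type`, `tissue_mpp`.
#' @return a [slide_map()].
#' @export
load_slide_map <- function(raster_path, cells_path, meta) {
  if (!file.exists(raster_path)) stop("missing raster file: ", raster_path)
  if (!file.exists(cells_path)) stop("missing cell table: ", cells_path)
  img <- png::readPNG(raster_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  raster <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  cells <- read.csv(cells_path, stringsAsFactors = FALSE)
  meta <- as.list(meta)
  slide_map(raster, cells,
            slide_id = meta$slide_id, patient_id = meta$patient_id,
            site_id = meta$site_id, cancer_type = meta$cancer_type,
            mpp = as.numeric(meta$tissue_mpp))
}

#' Write a slide map's raster and cell table to disk
#'
#' @param slide a [slide_map()].
#' @param raster_path,cells_path output paths (PNG, CSV).
#' @return invisibly, a metadata record suitable for [load_slide_map()].
#' @export
write_slide_map <- function(slide, raster_path, cells_path) {
  png::writePNG(slide$raster / 255, raster_path)
  write.csv(slide$cells, cells_path, row.names = FALSE)
  invisible(list(slide_id = slide$slide_id, patient_id = slide$patient_id,
                 site_id = slide$site_id, cancer_type = slide$cancer_type,
                 tissue_mpp = slide$mpp))
}

# 1-based pixel (row, col) containing each cell; cells are validated in-bounds
cell_pixels <- function(cells, mpp) {
  data.frame(row = floor(cells$y_um / mpp) + 1L,
             col = floor(cells$x_um / mpp) + 1L)
}

# logical vector: which cells fall inside a mask
cells_in_mask <- function(cells, mask, mpp) {
  if (nrow(cells) == 0) return(logical(0))
  px <- cell_pixels(cells, mpp)
  mask[cbind(px$row, px$col)]
}
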