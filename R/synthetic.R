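#' Synthetic scene parameters
#'
#' Describes one synthetic slide: a blob-like tissue geometry obtained by
#' thresholding smoothed Gaussian noise at fixed quantiles (background below
#' `q_tissue`; CAS between `q_tissue` and `q_ct`; CT above `q_ct`; necrosis
#' nested inside CT above `q_necrosis`, forming necrotic holes in tumor
#' cores), and per-class cell point processes restricted to each region.
#' Cells are homogeneous Poisson by default, or a Thomas cluster process for
#' classes listed in `cluster_process` (parents of intensity `kappa_mm2` per
#' mm^2, `Poisson(mu_offspring)` offspring scattered with isotropic Gaussian
#' spread `sigma_um`; parents and offspring falling outside the region are
#' truncated).
#'
#' Default intensities are plausible tumor-microenvironment densities:
#' lymphocytes enriched in stroma and around tumor, fibroblasts dominating
#' stroma, cancer cells dominating cancer tissue, sparse macrophages and
#' plasma cells, and a mostly acellular necrotic compartment.
#'
#' @param shape_px raster size (rows, cols) in pixels.
#' @param mpp microns per pixel (default 4).
#' @param smooth_px Gaussian smoothing scale of the geometry noise.
#' @param q_tissue,q_ct,q_necrosis threshold quantiles partitioning the field.
#' @param intensity 5 x 3 matrix of cells per mm^2 (classes x regions
#'   `ct`, `cas`, `necrosis`).
#' @param cluster_process named list per clustered class:
#'   `list(kappa_mm2=, mu_offspring=, sigma_um=)`.
#' @param geometry_seed,point_seed RNG seeds for the raster and the points.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(shape_px = c(160, 160), mpp = 4, smooth_px = 10,
                         q_tissue = 0.55, q_ct = 0.75, q_necrosis = 0.97,
                         intensity = default_intensity(),
                         cluster_process = list(
                           lymphocyte = list(kappa_mm2 = 40, mu_offspring = 15,
                                             sigma_um = 30)),
                         geometry_seed = 1, point_seed = 1) {
  stopifnot(length(shape_px) == 2, all(shape_px >= 8), mpp > 0,
            q_tissue < q_ct, q_ct < q_necrosis, q_necrosis <= 1)
  if (any(intensity < 0)) stop("cell intensities must be non-negative")
  structure(list(shape_px = as.integer(shape_px), mpp = mpp,
                 smooth_px = smooth_px, q_tissue = q_tissue, q_ct = q_ct,
                 q_necrosis = q_necrosis, intensity = intensity,
                 cluster_process = cluster_process,
                 geometry_seed = as.integer(geometry_seed),
                 point_seed = as.integer(point_seed)),
            class = "scene_params")
}

#' @rdname scene_params
#' @export
default_intensity <- function() {
  m <- rbind(
    lymphocyte = c(ct = 300, cas = 800, necrosis = 20),
    plasma     = c(ct = 50,  cas = 200, necrosis = 5),
    fibroblast = c(ct = 100, cas = 1000, necrosis = 10),
    macrophage = c(ct = 100, cas = 150, necrosis = 30),
    cancer     = c(ct = 2000, cas = 100, necrosis = 50))
  m[CELL_CLASSES, ]
}

#' Generate one synthetic slide map
#'
#' @param params a [scene_params()].
#' @param slide_id,patient_id,site_id,cancer_type metadata for the slide.
#' @return a [slide_map()], fully determined by the two seeds.
#' @export
generate_scene <- function(params, slide_id = "synthetic-1",
                           patient_id = slide_id, site_id = "site-1",
                           cancer_type = "SYN") {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$shape_px[1]; nc <- params$shape_px[2]
  set.seed(params$geometry_seed)
  field <- matrix(rnorm(nr * nc), nr, nc)
  field <- gauss_blur(field, sigma = params$smooth_px)
  qs <- quantile(field, c(params$q_tissue, params$q_ct, params$q_necrosis))
  raster <- matrix(TISSUE_CODES[["normal"]], nr, nc)
  raster[field >= qs[1]] <- TISSUE_CODES[["cas"]]
  raster[field >= qs[2]] <- TISSUE_CODES[["ct"]]
  raster[field >= qs[3]] <- TISSUE_CODES[["necrosis"]]

  set.seed(params$point_seed)
  px_mm2 <- (params$mpp / 1000)^2
  region_codes <- c(ct = TISSUE_CODES[["ct"]], cas = TISSUE_CODES[["cas"]],
                    necrosis = TISSUE_CODES[["necrosis"]])
  cells <- list(empty_cell_table())
  for (cls in CELL_CLASSES) {
    for (reg in colnames(params$intensity)) {
      lambda <- params$intensity[cls, reg]
      if (lambda == 0) next
      mask <- raster == region_codes[[reg]]
      n_px <- sum(mask)
      if (n_px == 0) {
        warning(sprintf("region %s empty but intensity %g requested for %s",
                        reg, lambda, cls))
        next
      }
      cp <- params$cluster_process[[cls]]
      pts <- if (is.null(cp)) {
        sample_poisson_points(mask, lambda * n_px * px_mm2, params$mpp)
      } else {
        sample_thomas_points(mask, lambda, cp, params$mpp, px_mm2)
      }
      if (nrow(pts)) {
        pts$cell_class <- cls
        cells[[length(cells) + 1]] <- pts
      }
    }
  }
  cells <- do.call(rbind, cells)
  slide_map(raster, cells, slide_id = slide_id, patient_id = patient_id,
            site_id = site_id, cancer_type = cancer_type, mpp = params$mpp)
}

# homogeneous Poisson points on a pixel mask: Poisson count, pixels sampled
# uniformly with replacement, uniform jitter within each pixel square
sample_poisson_points <- function(mask, expected_n, mpp) {
  n <- rpois(1, expected_n)
  if (n == 0) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  pix <- which(mask)
  sel <- pix[sample.int(length(pix), n, replace = TRUE)]
  r <- (sel - 1L) %% nrow(mask)       # 0-based row
  c0 <- (sel - 1L) %/% nrow(mask)     # 0-based col
  data.frame(x_um = (c0 + runif(n)) * mpp, y_um = (r + runif(n)) * mpp)
}

# Thomas cluster process on a mask; lambda is the target offspring intensity,
# so parent intensity kappa is taken from the process spec and offspring mean
# is rescaled to match lambda = kappa * mu. Offspring outside the region are
# truncated.
sample_thomas_points <- function(mask, lambda, cp, mpp, px_mm2) {
  area <- sum(mask) * px_mm2
  kappa <- cp$kappa_mm2
  mu <- lambda / kappa
  parents <- sample_poisson_points(mask, kappa * area, mpp)
  if (nrow(parents) == 0) return(parents)
  n_off <- rpois(nrow(parents), mu)
  tot <- sum(n_off)
  if (tot == 0) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  x <- rep(parents$x_um, n_off) + rnorm(tot, 0, cp$sigma_um)
  y <- rep(parents$y_um, n_off) + rnorm(tot, 0, cp$sigma_um)
  w_um <- ncol(mask) * mpp; h_um <- nrow(mask) * mpp
  keep <- x >= 0 & x < w_um & y >= 0 & y < h_um
  x <- x[keep]; y <- y[keep]
  inside <- mask[cbind(floor(y / mpp) + 1L, floor(x / mpp) + 1L)]
  data.frame(x_um = x[inside], y_um = y[inside])
}

#' Synthetic cohort specification
#'
#' @param n_patients number of patients (>= `n_sites`).
#' @param n_sites number of tissue source sites (>= 4 so a 20-30% site
#'   hold-out exists).
#' @param base_params template [scene_params()] for every slide.
#' @param site_sd log-normal SD of per-site, per-class intensity multipliers
#'   (multi-site batch structure).
#' @param slide_sd log-normal SD of per-slide intensity jitter.
#' @param second_slide_prob probability a patient contributes two slides.
#' @param n_active_clusters number of HIF clusters carrying true signal.
#' @param noise_sd phenotype noise SD relative to unit-variance signal.
#' @param master_seed master RNG seed; all randomness derives from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 60, n_sites = 8,
                        base_params = scene_params(), site_sd = 0.15,
                        slide_sd = 0.10, second_slide_prob = 0.3,
                        n_active_clusters = 2, noise_sd = 0.35,
                        master_seed = 1) {
  if (n_sites < 4) stop("need at least 4 sites for a site hold-out")
  if (n_patients < n_sites) stop("more sites than patients is infeasible")
  structure(list(n_patients = n_patients, n_sites = n_sites,
                 base_params = base_params, site_sd = site_sd,
                 slide_sd = slide_sd, second_slide_prob = second_slide_prob,
                 n_active_clusters = n_active_clusters, noise_sd = noise_sd,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Generates multi-site slides (1-2 per patient), extracts the full HIF
#' catalog from every slide, aggregates to patients, Z-scores pan-cohort,
#' clusters the HIFs, and finally simulates a continuous phenotype
#' `y = X beta + intercept + noise` where `X` are the *recomputed* Z-scored
#' HIFs and `beta` is nonzero only inside `n_active_clusters` randomly chosen
#' HIF clusters (scaled so the signal has unit variance). Because the
#' phenotype is built from re-extracted features rather than a stored
#' formula, any extraction defect breaks downstream recovery.
#'
#' @param spec a [cohort_spec()].
#' @param config a [hif_config()].
#' @param verbose print extraction progress.
#' @return list with `slides`, `outcomes` (patient_id, phenotype),
#'   `truth` (beta_true, active_clusters, clusters, noise_sd), `hifs_slide`,
#'   `hifs_patient` (z-scored), `manifest`.
#' @export
generate_cohort <- function(spec, config = hif_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$master_seed)
  seed_pool <- function() sample.int(2147483646L, 1)
  sites <- sprintf("site-%02d", seq_len(spec$n_sites))
  site_of <- sample(rep(sites, length.out = spec$n_patients))
  site_factor <- matrix(exp(rnorm(spec$n_sites * length(CELL_CLASSES), 0, spec$site_sd)),
                        spec$n_sites, length(CELL_CLASSES),
                        dimnames = list(sites, CELL_CLASSES))
  slides <- list()
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("patient-%03d", i)
    n_slides <- 1L + rbinom(1, 1, spec$second_slide_prob)
    for (s in seq_len(n_slides)) {
      p <- spec$base_params
      scalef <- runif(1, 0.8, 1.2)
      p$shape_px <- pmax(32L, as.integer(round(p$shape_px * scalef)))
      jitter <- exp(rnorm(length(CELL_CLASSES), 0, spec$slide_sd))
      p$intensity <- p$intensity * site_factor[site_of[i], ] * jitter
      p$geometry_seed <- seed_pool()
      p$point_seed <- seed_pool()
      slides[[length(slides) + 1]] <-
        generate_scene(p, slide_id = sprintf("%s-s%d", pid, s),
                       patient_id = pid, site_id = site_of[i],
                       cancer_type = "SYN")
    }
  }
  pheno_seed <- seed_pool()
  manifest <- hif_manifest(config)
  hm_slide <- extract_cohort(slides, manifest, config, verbose = verbose)
  hm_pat <- zscore_hifs(aggregate_patients(hm_slide))
  clusters <- cluster_hifs(hm_pat, cutoff = config$cluster_cutoff)
  truth <- simulate_phenotype(hm_pat, clusters, spec$n_active_clusters,
                              spec$noise_sd, pheno_seed)
  list(slides = slides,
       outcomes = data.frame(patient_id = rownames(hm_pat$values),
                             phenotype = truth$y, stringsAsFactors = FALSE),
       truth = truth[c("beta_true", "active_clusters", "noise_sd")],
       clusters = clusters, hifs_slide = hm_slide, hifs_patient = hm_pat,
       manifest = manifest)
}

# draw a group-sparse true coefficient vector on the HIF clusters and the
# resulting noisy continuous phenotype (signal scaled to unit variance)
simulate_phenotype <- function(hm_pat, clusters, n_active, noise_sd, seed) {
  set.seed(seed)
  x <- hm_pat$values
  sizes <- table(clusters$assignment)
  eligible <- as.integer(names(sizes)[sizes >= 3])
  # prefer clusters whose members actually vary across the cohort
  varying <- vapply(eligible, function(cl) {
    cols <- names(clusters$assignment)[clusters$assignment == cl]
    all(apply(x[, cols, drop = FALSE], 2, sd) > 0)
  }, TRUE)
  eligible <- eligible[varying]
  if (length(eligible) < n_active)
    stop("not enough eligible HIF clusters to plant signal in")
  active <- sort(sample(eligible, n_active))
  beta <- setNames(numeric(ncol(x)), colnames(x))
  for (cl in active) {
    cols <- names(clusters$assignment)[clusters$assignment == cl]
    beta[cols] <- rnorm(length(cols))
  }
  signal <- drop(x %*% beta)
  s <- sd(signal)
  if (s > 0) {
    beta <- beta / s
    signal <- signal / s
  }
  y <- signal + rnorm(nrow(x), 0, noise_sd)
  list(beta_true = beta, active_clusters = active, noise_sd = noise_sd, y = y)
}
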