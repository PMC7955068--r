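#' Site-held-out train/hold-out split
#'
#' Defines a hold-out set of approximately 20-30% of patients drawn entirely
#' from tissue source sites unseen in training: sites are shuffled by the
#' seed and greedily added to the hold-out (skipping sites that would
#' overshoot the upper bound) until the patient fraction enters the target
#' range. If no subset reaches the range, the closest achievable fraction is
#' used with a warning.
#'
#' @param meta data frame with `patient_id` and `site_id` (one row per
#'   patient).
#' @param frac_range target hold-out patient fraction range.
#' @param seed RNG seed; the split is deterministic per seed.
#' @return list with `train` and `holdout` patient id vectors plus
#'   `holdout_sites` and `holdout_frac`.
#' @export
site_holdout_split <- function(meta, frac_range = c(0.20, 0.30), seed = 1) {
  stopifnot(all(c("patient_id", "site_id") %in% names(meta)))
  meta <- meta[!duplicated(meta$patient_id), ]
  n <- nrow(meta)
  sites <- unique(meta$site_id)
  set.seed(seed)
  sites <- sample(sites)
  site_n <- table(meta$site_id)
  chosen <- character(0)
  cur <- 0
  for (s in sites) {
    cand <- cur + site_n[[s]]
    if (cand / n > frac_range[2]) next
    chosen <- c(chosen, s)
    cur <- cand
    if (cur / n >= frac_range[1]) break
  }
  if (cur / n < frac_range[1]) {
    # no subset landed inside the range: take the single closest achievable
    best <- sites[which.min(abs(as.numeric(site_n[sites]) / n - mean(frac_range)))]
    chosen <- best
    cur <- site_n[[best]]
    warning(sprintf("no site subset reaches a %.0f-%.0f%% hold-out; using %.1f%%",
                    100 * frac_range[1], 100 * frac_range[2], 100 * cur / n))
  }
  hold <- meta$patient_id[meta$site_id %in% chosen]
  list(train = setdiff(meta$patient_id, hold), holdout = hold,
       holdout_sites = chosen, holdout_frac = cur / n)
}
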