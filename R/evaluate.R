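#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity with mid-ranks, so tied scores
#' contribute one half; invariant under strictly monotone transforms of the
#' scores. Constant scores give 0.5.
#'
#' @param probs predicted scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(probs, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integral: scores are scanned in decreasing order
#' (tied scores form a single threshold), and each recall increment
#' contributes the precision at that threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(probs, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  s <- probs[ord]; l <- labels[ord]
  cum_tp <- cumsum(l)
  cum_n <- seq_along(l)
  thresh <- which(c(s[-1] != s[-length(s)], TRUE)) # last index of each tie block
  tp <- cum_tp[thresh]; nn <- cum_n[thresh]
  prec <- tp / nn
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate classifier probabilities with bootstrap uncertainty
#'
#' AUROC (Mann-Whitney identity) and AUPRC (step-interpolated) with
#' percentile bootstrap confidence intervals over paired resamples of
#' (probability, label); degenerate resamples missing a class are redrawn.
#' The p-value of each metric is the fraction of bootstrap metrics below 0.5
#' (chance level); correct across a task battery with [bh_correct()].
#'
#' @inheritParams auroc
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list with `auroc`, `auprc`, `auroc_ci`, `auprc_ci`, `auroc_p`,
#'   `auprc_p`, `n_boot`.
#' @export
evaluate_predictions <- function(probs, labels, n_boot = 1000, seed = 1,
                                 conf = 0.95) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  n <- length(labels)
  boot_roc <- numeric(n_boot); boot_prc <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    boot_roc[b] <- auroc(probs[idx], labels[idx])
    boot_prc[b] <- auprc(probs[idx], labels[idx])
  }
  alpha <- (1 - conf) / 2
  list(auroc = auroc(probs, labels), auprc = auprc(probs, labels),
       auroc_ci = unname(quantile(boot_roc, c(alpha, 1 - alpha))),
       auprc_ci = unname(quantile(boot_prc, c(alpha, 1 - alpha))),
       auroc_p = mean(boot_roc < 0.5), auprc_p = mean(boot_prc < 0.5),
       n_boot = n_boot)
}
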