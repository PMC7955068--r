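#' Binarize a continuous molecular outcome with a two-component GMM
#'
#' Fits a one-dimensional two-component Gaussian mixture with unequal
#' variances (EM with deterministic model-based hierarchical initialization)
#' and labels samples high/low at the intersection of the two weighted
#' component densities between the component means: the root of
#' `pi1 * N(x | mu1, s1^2) = pi2 * N(x | mu2, s2^2)`, solved in closed form
#' (quadratic in x) and clamped to `[mu1, mu2]`. Values at or above the
#' threshold are labeled high (1).
#'
#' @param values continuous per-patient outcome, `n >= 20`.
#' @return object of class `binarization_model`: `pi`, `mu`, `sigma`,
#'   `threshold`, `labels` (0/1 integer vector).
#' @export
gmm_binarize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 20) stop("need at least 20 observations")
  if (sd(values) == 0) stop("values are constant; no mixture exists")
  fit <- Mclust(values, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    # unequal-variance EM can degenerate at small n; fall back to the
    # equal-variance mixture before giving up
    fit <- Mclust(values, G = 2, modelNames = "E", verbose = FALSE)
  }
  if (is.null(fit)) stop("mixture fit failed to converge")
  mu <- fit$parameters$mean
  s2 <- fit$parameters$variance$sigmasq
  if (length(s2) == 1) s2 <- rep(s2, 2)
  # variance floor guards EM degeneracies
  s2 <- pmax(s2, 1e-6 * stats::var(values))
  pr <- fit$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; s2 <- s2[ord]; pr <- pr[ord]
  thr <- density_intersection(pr, mu, sqrt(s2))
  labels <- as.integer(values >= thr)
  structure(list(pi = pr, mu = mu, sigma = sqrt(s2), threshold = thr,
                 labels = labels),
            class = "binarization_model")
}

# root of pi1 N(x|mu1,s1) = pi2 N(x|mu2,s2) between the means, in closed form
density_intersection <- function(pr, mu, s) {
  # log pi1 - log s1 - (x-mu1)^2/(2 s1^2) = log pi2 - log s2 - (x-mu2)^2/(2 s2^2)
  a <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  b <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  cc <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log(pr[1]) - log(pr[2]) + log(s[2]) - log(s[1])
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots >= mu[1] & roots <= mu[2]]
  if (length(inside)) return(inside[1])
  if (length(roots)) {
    mid <- mean(mu)
    return(min(max(roots[which.min(abs(roots - mid))], mu[1]), mu[2]))
  }
  mean(mu)
}

#' @export
print.binarization_model <- function(x, ...) {
  cat(sprintf("<binarization_model> pi = (%.2f, %.2f), mu = (%.3f, %.3f), threshold = %.3f\n",
              x$pi[1], x$pi[2], x$mu[1], x$mu[2], x$threshold))
  invisible(x)
}
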