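# Bivariate-normal maximum-likelihood fits and the LR statistic.
#
# The alternative model gives each marker genotype class its own bivariate
# mean vector while all classes share one 2x2 covariance matrix
# Sigma = [[s1^2, rho*s1*s2], [rho*s1*s2, s2^2]]; the null collapses the
# class means to a single grand mean with its own freely estimated Sigma.
# Both MLEs are closed form (class/grand sample means; pooled within-class /
# total scatter divided by n), but the log-likelihood is evaluated by
# summing the bivariate-normal log density over individuals so that it can
# be checked independently against the Wilks-Lambda determinant identity.

skip_marker <- function(reason) {
  stop(errorCondition(reason, class = c("covqtl_skip", "error", "condition")))
}

# sum of log N2(y_i; mu_i, Sigma); mu is an n x 2 matrix (or length-2 vector)
bvn_loglik <- function(y, mu, Sigma) {
  if (!is.matrix(mu)) mu <- matrix(mu, nrow(y), 2L, byrow = TRUE)
  d <- y - mu
  det_s <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (!is.finite(det_s) || det_s <= 0) skip_marker("singular covariance matrix")
  q <- (Sigma[2, 2] * d[, 1]^2 - 2 * Sigma[1, 2] * d[, 1] * d[, 2] +
          Sigma[1, 1] * d[, 2]^2) / det_s
  sum(-log(2 * pi) - 0.5 * log(det_s) - 0.5 * q)
}

new_bivariate_fit <- function(class_means, Sigma, loglik, n_per_class) {
  structure(
    list(class_means = class_means,
         sigma1_sq = Sigma[1, 1], sigma2_sq = Sigma[2, 2],
         rho = Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2]),
         Sigma = Sigma, loglik = loglik,
         n_per_class = n_per_class, n = sum(n_per_class)),
    class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("bivariate_fit: %d class(es), n = %d, loglik = %.4f\n",
              nrow(x$class_means), x$n, x$loglik))
  cat(sprintf("  sigma1^2 = %.4g, sigma2^2 = %.4g, rho = %.4f\n",
              x$sigma1_sq, x$sigma2_sq, x$rho))
  invisible(x)
}

#' Null-model fit: one bivariate mean for the whole population
#'
#' MLE of a single bivariate normal: grand mean vector and total-scatter
#' covariance `S0/n`.
#'
#' @param y numeric n x 2 matrix of trait pairs, no missing values, n >= 3.
#' @return A `bivariate_fit` with one row of `class_means`.
#' @export
fit_h0 <- function(y) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2L)
  if (anyNA(y)) stop("fit_h0 requires complete cases")
  n <- nrow(y)
  if (n < 3L) stop("fit_h0 needs at least 3 individuals")
  mu <- colMeans(y)
  d <- sweep(y, 2L, mu)
  Sigma <- crossprod(d) / n
  if (Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2 <= 0) {
    stop("singular covariance matrix under H0 (a trait is constant or the ",
         "traits are perfectly collinear)")
  }
  ll <- bvn_loglik(y, mu, Sigma)
  new_bivariate_fit(matrix(mu, 1L, 2L, dimnames = list("all", NULL)),
                    Sigma, ll, stats::setNames(n, "all"))
}

#' Alternative-model fit: genotype-class means with pooled covariance
#'
#' MLE under the covariation-QTL model: each genotype class gets its own
#' mean vector, all classes share the pooled covariance
#' `Sigma = (1/n) * sum_j sum_{i in j} (y_i - mu_j)(y_i - mu_j)'`.
#'
#' @param y numeric n x 2 matrix of trait pairs, no missing values.
#' @param classes genotype class labels, length n.
#' @param min_class_size smallest class size accepted; a smaller class
#'   raises a classed condition (`covqtl_skip`) so that genome scans can
#'   skip the marker with a logged reason.
#' @return A `bivariate_fit` with one `class_means` row per class.
#' @export
fit_h1 <- function(y, classes, min_class_size = 5L) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2L, length(classes) == nrow(y))
  if (anyNA(y) || anyNA(classes)) stop("fit_h1 requires complete cases")
  f <- factor(classes)
  k <- nlevels(f)
  if (k < 2L) skip_marker("monomorphic: fewer than 2 genotype classes")
  nj <- tabulate(f, k)
  if (any(nj < min_class_size)) {
    skip_marker(sprintf("class too small (min %d < %d)", min(nj), min_class_size))
  }
  n <- nrow(y)
  mu <- rowsum(y, f) / nj
  d <- y - mu[as.integer(f), , drop = FALSE]
  Sigma <- crossprod(d) / n
  if (Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2 <= 0) {
    skip_marker("singular pooled covariance matrix")
  }
  ll <- bvn_loglik(y, mu[as.integer(f), , drop = FALSE], Sigma)
  dimnames(mu) <- list(levels(f), NULL)
  new_bivariate_fit(mu, Sigma, ll, stats::setNames(nj, levels(f)))
}

#' Log-likelihood-ratio statistic for one marker
#'
#' `LR = 2 * (loglik_H1 - loglik_H0)` on the chi-square scale, with
#' `df = 2 * (k - 1)` for `k` genotype classes (2 for testcross, 4 for
#' intercross markers).  Both fits must come from the same complete-case
#' subset; nesting of the models guarantees LR >= 0, so values below
#' -1e-8 signal an internal error while tiny negative rounding is clamped
#' to zero.
#'
#' @param fit0 `bivariate_fit` from [fit_h0()].
#' @param fit1 `bivariate_fit` from [fit_h1()].
#' @return list with elements `lr` and `df`.
#' @export
lr_statistic <- function(fit0, fit1) {
  if (fit0$n != fit1$n) {
    stop("H0 and H1 fits use different numbers of individuals")
  }
  lr <- 2 * (fit1$loglik - fit0$loglik)
  if (lr < -1e-8) {
    stop("negative LR beyond numerical tolerance (", format(lr),
         "): MLE violation")
  }
  if (lr < 0) lr <- 0
  list(lr = lr, df = 2L * (nrow(fit1$class_means) - 1L))
}
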