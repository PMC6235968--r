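# Monte-Carlo correlation between protein and mRNA stage profiles measured
# on disjoint biological replicates, with Fisher-transform confidence
# intervals, plus the max-normalization used for joint plotting.

#' Fisher transformation and its inverse
#'
#' `fisher_z` maps a correlation to `atanh(r)` after clipping `|r|` at
#' `1 - 1e-12` (so degenerate perfect correlations from zero-SE draws stay
#' finite); `fisher_z_inv` maps back with `tanh`.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("|r| > 1 is not a correlation")
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Monte-Carlo correlation of two mean/SE profiles
#'
#' Protein and transcript profiles come from different biological
#' replicates, so their structural correlation cannot be computed directly.
#' Instead, `n_datasets` random profile pairs are drawn with the same
#' distribution properties as the observed ones - each stage value
#' independently Normal(mean, SE) - and a Pearson correlation is computed
#' for each draw. The summary correlation is the mean on the Fisher-z
#' scale mapped back through `tanh`, and the 95% confidence interval comes
#' from the 2.5/97.5 percentiles of the z samples (or mean +/- 1.96 sd of
#' z under `ci_method = "normal"`). The pair is called significant when
#' the interval excludes zero.
#'
#' @param a,b Data frames with columns `stage`, `mean`, `se` in a shared
#'   stage order (length >= 3).
#' @param n_datasets Number of random datasets (default 1500).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"percentile"` (default) or `"normal"` combination of
#'   the z samples.
#' @param point `"mean_z"` (default, `tanh(mean(atanh(r)))`) or `"mean_r"`.
#' @return A `correlation_result` list: `r_samples`, `z_samples`,
#'   `r_point`, `ci_low`, `ci_high`, `significant`, `n_datasets`, `seed`.
#' @export
monte_carlo_correlation <- function(a, b, n_datasets = 1500L, seed = 1L,
                                    conf_level = 0.95,
                                    ci_method = c("percentile", "normal"),
                                    point = c("mean_z", "mean_r")) {
  ci_method <- match.arg(ci_method)
  point <- match.arg(point)
  k <- nrow(a)
  if (nrow(b) != k) stop("profiles must share the stage grid")
  if (!is.null(a$stage) && !is.null(b$stage) &&
      !identical(as.character(a$stage), as.character(b$stage)))
    stop("profiles must share the stage order")
  if (k < 3L) stop("correlation needs at least 3 stages")
  if (any(a$se < 0) || any(b$se < 0)) stop("standard errors must be >= 0")
  set.seed(seed)
  # canonical stream assignment so that (a, b) and (b, a) under the same
  # seed yield bit-identical r samples (the procedure is symmetric)
  Z1 <- matrix(stats::rnorm(k * n_datasets), nrow = k)
  Z2 <- matrix(stats::rnorm(k * n_datasets), nrow = k)
  key <- function(p) paste(format(p$mean, digits = 15), collapse = ",")
  if (key(a) > key(b)) { tmp <- Z1; Z1 <- Z2; Z2 <- tmp }
  A <- a$mean + a$se * Z1
  B <- b$mean + b$se * Z2
  Ac <- A - matrix(colMeans(A), k, n_datasets, byrow = TRUE)
  Bc <- B - matrix(colMeans(B), k, n_datasets, byrow = TRUE)
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  r <- ifelse(den > 0, num / den, 0)
  z <- fisher_z(r)
  r_point <- if (point == "mean_z") fisher_z_inv(mean(z)) else mean(r)
  alpha <- 1 - conf_level
  if (ci_method == "percentile") {
    qs <- stats::quantile(z, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    qs <- mean(z) + c(-1, 1) * stats::qnorm(1 - alpha / 2) * stats::sd(z)
  }
  ci <- fisher_z_inv(qs)
  structure(list(r_samples = r, z_samples = z, r_point = r_point,
                 ci_low = ci[1L], ci_high = ci[2L],
                 significant = ci[1L] > 0 || ci[2L] < 0,
                 n_datasets = as.integer(n_datasets), seed = seed,
                 conf_level = conf_level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo correlation (%d datasets, seed %s)\n",
              x$n_datasets, format(x$seed)))
  cat(sprintf("  r = %.3f, %.0f%% CI [%.3f, %.3f], %s\n", x$r_point,
              100 * x$conf_level, x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Normalize profiles for joint plotting
#'
#' Divides each profile's means and standard errors by that profile's
#' maximum mean, so both profiles peak at 1 and can share an axis.
#' Idempotent on already-normalized profiles.
#'
#' @param a,b Data frames with columns `mean` and `se`.
#' @return List with rescaled `a` and `b`.
#' @export
normalize_profiles <- function(a, b) {
  scale1 <- function(p) {
    m <- max(p$mean)
    if (m <= 0) stop("profile maximum must be positive")
    p$mean <- p$mean / m
    p$se <- p$se / m
    p
  }
  list(a = scale1(a), b = scale1(b))
}
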