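#' Fit a mean-variance model from unselected input libraries
#'
#' Sequencing counts of a pooled library are overdispersed relative to
#' Poisson; replicate unselected (input) samples carry that dispersion
#' without any selection signal, so they are used to learn the relationship
#' between a guide's mean normalized count and its variance. The model is
#' \deqn{var(\mu) = \mu + e^{a}\mu^{b}.} Guides are grouped into bins of
#' equal size by mean count, and the average excess variance
#' `mean(var - mean)` is computed per bin; averaging before taking logs
#' avoids the selection bias of fitting only guides whose noisy sample
#' variance happens to exceed their mean. `a` and `b` come from least
#' squares of `log(excess)` on `log(mean)` over the bins with positive
#' excess. With fewer than two input replicates, or fewer than three
#' positive-excess bins, the fit falls back to a Poisson model
#' (`var = mean`) with a warning.
#'
#' @param input_norm numeric matrix of normalized counts, guides x input
#'   replicates.
#' @param min_guides minimum number of guides with positive mean required;
#'   default 50.
#' @param eps relative threshold: a bin counts as overdispersed when its
#'   mean excess variance exceeds `eps` times its mean count; default 1e-8.
#' @return object of class `mean_variance_model` with elements `a`, `b`,
#'   `n_points` (bins used in the fit), `poisson` (logical fallback flag),
#'   `eps`.
#' @export
fit_mean_variance <- function(input_norm, min_guides = 50, eps = 1e-8) {
  m <- as.matrix(input_norm)
  poisson_model <- structure(
    list(a = -Inf, b = 0, n_points = 0L, poisson = TRUE, eps = eps),
    class = "mean_variance_model")
  if (ncol(m) < 2L) {
    warning("fewer than 2 input samples; falling back to a Poisson ",
            "variance model (var = mean)", call. = FALSE)
    return(poisson_model)
  }
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  if (sum(mu > 0) < min_guides)
    stop("need at least ", min_guides, " guides with positive mean to fit ",
         "the mean-variance model", call. = FALSE)
  keep <- mu > 0
  mu <- mu[keep]
  v <- v[keep]
  ord <- order(mu)
  n <- length(mu)
  n_bins <- max(10L, min(30L, n %/% 50L))
  bin <- ceiling(seq_along(ord) / (n / n_bins))
  mu_bin <- tapply(mu[ord], bin, mean)
  ex_bin <- tapply(v[ord] - mu[ord], bin, mean)
  pos <- is.finite(ex_bin) & ex_bin > eps * mu_bin
  if (sum(pos) < 3L) {
    warning("no overdispersion detected in input replicates; falling back ",
            "to a Poisson variance model", call. = FALSE)
    return(poisson_model)
  }
  x <- log(mu_bin[pos])
  y <- log(ex_bin[pos])
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(a = unname(fit$coefficients[1L]),
                 b = unname(fit$coefficients[2L]),
                 n_points = sum(pos), poisson = FALSE, eps = eps),
            class = "mean_variance_model")
}

#' Predicted count variance at a given mean
#'
#' @param model a [fit_mean_variance()] model.
#' @param mu vector of (normalized) mean counts.
#' @return predicted variances, always at least `mu`.
#' @export
predict_variance <- function(model, mu) {
  stopifnot(inherits(model, "mean_variance_model"))
  if (model$poisson) return(mu)
  pmax(mu + exp(model$a) * mu^model$b, mu)
}

#' @export
print.mean_variance_model <- function(x, ...) {
  if (x$poisson) {
    cat("mean_variance_model: Poisson (var = mean) fallback\n")
  } else {
    cat(sprintf(
      "mean_variance_model: var(mu) = mu + exp(%.4f) * mu^%.4f  (%d guides)\n",
      x$a, x$b, x$n_points))
  }
  invisible(x)
}
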