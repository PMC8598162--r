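# Guide-level enrichment testing between sorted bins.

# Continuity-corrected upper-tail probability P(X >= obs) for a count
# distribution with the given mean and variance: negative binomial when
# var > mean, Poisson otherwise. Implemented as the linearly interpolated
# survival function evaluated at obs - 0.5, which equals the mid-P tail
# for integer observations and varies smoothly for real-valued normalized
# counts. Vectorized over obs/mean/var.
count_upper_tail <- function(obs, mean, var) {
  n <- length(obs)
  mean <- rep_len(mean, n)
  var <- rep_len(var, n)
  p <- rep(1, n)
  ok <- mean > 0
  if (!any(ok)) return(p)
  q <- obs - 0.5
  k <- floor(q)
  f <- q - k
  surv <- function(j, idx) {
    # P(X > j) for the model at idx; j may be < 0 (survival = 1)
    out <- rep(1, length(idx))
    pos <- j >= 0
    if (any(pos)) {
      i <- idx[pos]
      use_nb <- var[i] > mean[i] * (1 + 1e-8)
      res <- numeric(sum(pos))
      if (any(use_nb)) {
        ii <- i[use_nb]
        size <- mean[ii]^2 / (var[ii] - mean[ii])
        res[use_nb] <- stats::pnbinom(j[pos][use_nb], size = size,
                                      mu = mean[ii], lower.tail = FALSE)
      }
      if (any(!use_nb)) {
        ii <- i[!use_nb]
        res[!use_nb] <- stats::ppois(j[pos][!use_nb], lambda = mean[ii],
                                     lower.tail = FALSE)
      }
      out[pos] <- res
    }
    out
  }
  idx <- which(ok)
  s0 <- surv(k[idx], idx)
  s1 <- surv(k[idx] + 1L, idx)
  p[idx] <- (1 - f[idx]) * s0 + f[idx] * s1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# Re-express model p-values as empirical tail probabilities within the
# control-guide p distribution. Strictly monotone (preserves every
# ranking): the control ECDF is interpolated linearly in log(p) between
# the sorted control p-values, scaled proportionally below the smallest
# control p, and interpolated toward 1 above the largest, so guides more
# extreme than every control remain fully resolved.
calibrate_to_controls <- function(p, ref) {
  ref <- sort(ref)
  n <- length(ref)
  if (n < 1L) stop("empty control reference", call. = FALSE)
  y <- seq_len(n) / (n + 1)
  # collapse duplicated reference values to their largest ECDF height
  keep <- !duplicated(ref, fromLast = TRUE)
  xk <- log(ref[keep])
  yk <- y[keep]
  out <- numeric(length(p))
  lo <- p < ref[1L]
  hi <- p > ref[n]
  mid <- !lo & !hi
  if (any(mid)) {
    out[mid] <- if (length(xk) == 1L) yk
    else stats::approx(xk, yk, xout = log(p[mid]), rule = 2,
                       ties = "ordered")$y
  }
  # below the smallest control p: proportional on the raw scale
  out[lo] <- y[1L] * p[lo] / ref[1L]
  # above the largest: interpolate in log(p) toward p = 1
  if (any(hi)) {
    out[hi] <- if (ref[n] >= 1) 1
    else yk[length(yk)] + (1 - yk[length(yk)]) *
      (1 - log(p[hi]) / log(ref[n]))
  }
  pmin(pmax(out, .Machine$double.xmin), 1)
}

#' Per-guide enrichment test between sorted bins
#'
#' Tests, for every guide, the null hypothesis that its abundance is the
#' same in the phenotype-high and phenotype-low bins. The expected count is
#' estimated as the average of the guide's normalized high- and low-bin
#' counts; its variance comes from the input-derived
#' [mean_variance_model][fit_mean_variance()]. With the default
#' `combine = "sum"`, normalized counts are summed over replicates and the
#' sum is tested against a negative binomial whose mean and variance are
#' the per-replicate values propagated across replicates;
#' `combine = "fisher"` tests each replicate and combines one-sided
#' p-values by Fisher's method. `p_low` is the upper-tail probability of
#' the observed low-bin count (enrichment among cells that fail to induce
#' the phenotype, the loss-of-function direction), `p_high` the symmetric
#' statistic for the high bin, and `p_twosided = min(1, 2 min(p_low,
#' p_high))`.
#'
#' When a control-guide set is supplied (the default pipeline behaviour),
#' model p-values are re-expressed as empirical tail probabilities within
#' the control-guide p-value distribution. This strictly monotone transform
#' leaves all rankings — and hence the gene-level rank aggregation —
#' unchanged, while making null p-values uniform even where the
#' input-derived variance model cannot capture bin-level sampling
#' overdispersion. Set `calibrate = "none"` for the raw model tails.
#'
#' @param norm a normalized [screen_counts] (see [normalize_counts()])
#'   containing at least one `bin_high`/`bin_low` replicate pair.
#' @param model a [fit_mean_variance()] model.
#' @param library optional [guide_library] used to attach `gene_id`/`role`.
#' @param control character vector of control guide ids used for
#'   calibration (ignored when `calibrate = "none"`).
#' @param calibrate `"control"` (default) or `"none"`.
#' @param combine `"sum"` (default) or `"fisher"`.
#' @param lfc_pseudocount pseudocount added to normalized means for the
#'   reported log fold change only (never for p-values); default 1.
#' @return data frame of class `guide_stats` with columns `guide_id`,
#'   `gene_id`, `role`, `input_mean`, `high_mean`, `low_mean`,
#'   `lfc_hi_over_low` (log2 high/low, the reporting orientation),
#'   `p_low`, `p_high`, `p_twosided`, `zero_flag`.
#' @export
guide_test <- function(norm, model, library = NULL, control = NULL,
                       calibrate = c("control", "none"),
                       combine = c("sum", "fisher"), lfc_pseudocount = 1) {
  calibrate <- match.arg(calibrate)
  combine <- match.arg(combine)
  stopifnot(inherits(norm, "screen_counts"))
  if (!norm$normalized)
    warning("guide_test called on raw counts; normalize first", call. = FALSE)
  smp <- norm$samples
  hi <- smp[smp$role == "bin_high", , drop = FALSE]
  lo <- smp[smp$role == "bin_low", , drop = FALSE]
  reps <- intersect(hi$replicate, lo$replicate)
  if (!length(reps))
    stop("need at least one bin_high/bin_low pair sharing a replicate label",
         call. = FALSE)
  H <- norm$counts[, hi$sample[match(reps, hi$replicate)], drop = FALSE]
  L <- norm$counts[, lo$sample[match(reps, lo$replicate)], drop = FALSE]
  R <- length(reps)
  mu_rep <- (H + L) / 2
  mu_hat <- rowMeans(mu_rep)

  if (combine == "sum") {
    v1 <- predict_variance(model, mu_hat)
    mean_sum <- R * mu_hat
    var_sum <- R * v1
    p_low <- count_upper_tail(rowSums(L), mean_sum, var_sum)
    p_high <- count_upper_tail(rowSums(H), mean_sum, var_sum)
  } else {
    acc_lo <- acc_hi <- 0
    for (r in seq_len(R)) {
      vr <- predict_variance(model, mu_rep[, r])
      acc_lo <- acc_lo +
        log(count_upper_tail(L[, r], mu_rep[, r], vr))
      acc_hi <- acc_hi +
        log(count_upper_tail(H[, r], mu_rep[, r], vr))
    }
    p_low <- stats::pchisq(-2 * acc_lo, df = 2 * R, lower.tail = FALSE)
    p_high <- stats::pchisq(-2 * acc_hi, df = 2 * R, lower.tail = FALSE)
  }
  zero <- mu_hat == 0
  p_low[zero] <- 1
  p_high[zero] <- 1

  if (calibrate == "control") {
    if (is.null(control) || !length(intersect(control, rownames(norm$counts))))
      stop("calibrate = \"control\" requires a non-empty control guide set; ",
           "use calibrate = \"none\" for raw model p-values", call. = FALSE)
    ctrl <- intersect(control, rownames(norm$counts))
    in_ctrl <- rownames(norm$counts) %in% ctrl
    p_low <- calibrate_to_controls(p_low, p_low[in_ctrl])
    p_high <- calibrate_to_controls(p_high, p_high[in_ctrl])
  }

  input_cols <- smp$sample[smp$role == "input"]
  input_mean <- if (length(input_cols))
    rowMeans(norm$counts[, input_cols, drop = FALSE]) else NA_real_
  high_mean <- rowMeans(H)
  low_mean <- rowMeans(L)
  out <- data.frame(
    guide_id = rownames(norm$counts),
    gene_id = NA_character_, role = NA_character_,
    input_mean = input_mean, high_mean = high_mean, low_mean = low_mean,
    lfc_hi_over_low = log2((high_mean + lfc_pseudocount) /
                             (low_mean + lfc_pseudocount)),
    p_low = p_low, p_high = p_high,
    p_twosided = pmin(1, 2 * pmin(p_low, p_high)),
    zero_flag = zero, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(library)) {
    i <- match(out$guide_id, library$guide_id)
    out$gene_id <- library$gene_id[i]
    out$role <- library$role[i]
  }
  class(out) <- c("guide_stats", "data.frame")
  out
}
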