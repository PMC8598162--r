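# Alpha-thresholded robust rank aggregation (alpha-RRA) of guides to genes.

#' Percentile ranks of guides by enrichment p-value
#'
#' Converts one-sided guide p-values to percentiles `u = rank/n` in (0, 1],
#' with average ranks for ties. All scored guides — including the negative
#' controls, which anchor the null rank pool — enter the denominator. The
#' percentiles are invariant under any strictly monotone transform of the
#' p-values.
#'
#' @param guide_stats a [guide_test()] result (or a numeric p-value vector).
#' @param direction `"low_enrichment"` (rank by `p_low`; loss-of-function
#'   direction for a positive regulator) or `"high_enrichment"` (`p_high`).
#' @return numeric vector of percentiles in (0, 1], named by guide id when
#'   available.
#' @export
guide_percentiles <- function(guide_stats,
                              direction = c("low_enrichment",
                                            "high_enrichment")) {
  direction <- match.arg(direction)
  p <- if (is.numeric(guide_stats)) guide_stats
  else if (direction == "low_enrichment") guide_stats$p_low
  else guide_stats$p_high
  u <- rank(p, ties.method = "average") / length(p)
  if (!is.numeric(guide_stats)) names(u) <- guide_stats$guide_id
  u
}

#' Robust rank aggregation score for one gene
#'
#' Given the sorted percentiles `u(1) <= ... <= u(m)` of the gene's guides
#' that pass the alpha threshold, computes
#' `beta_i = P(Beta(i, m - i + 1) <= u(i))` — the probability that the
#' i-th order statistic of m uniform ranks is at least as extreme — and
#' returns `rho = min_i beta_i`. A gene with no passing guides scores
#' `rho = 1`. Filtering low-ranking guides before aggregation makes the
#' score robust to inactive guides in the gene's set.
#'
#' @param u_selected percentiles in (0, 1] of the selected guides (any
#'   order; may be empty).
#' @return the rho score in (0, 1].
#' @export
rra_rho <- function(u_selected) {
  m <- length(u_selected)
  if (m == 0L) return(1)
  if (any(!is.finite(u_selected)) || any(u_selected <= 0) ||
      any(u_selected > 1))
    stop("percentiles must lie in (0, 1]", call. = FALSE)
  u <- sort(u_selected)
  i <- seq_len(m)
  min(stats::pbeta(u, i, m - i + 1))
}

# Vectorized rho over rows of a percentile matrix U (n x k), selecting
# entries <= u_cut. Row-sorts via a pmin/pmax sorting network (k is small).
rra_rho_rows <- function(U, u_cut) {
  n <- nrow(U)
  k <- ncol(U)
  sel <- U <= u_cut
  m <- rowSums(sel)
  W <- U
  W[!sel] <- Inf
  for (pass in seq_len(k)) {
    for (j in seq_len(k - 1L)) {
      a <- W[, j]
      b <- W[, j + 1L]
      W[, j] <- pmin(a, b)
      W[, j + 1L] <- pmax(a, b)
    }
  }
  rho <- rep(1, n)
  for (i in seq_len(k)) {
    act <- m >= i
    if (!any(act)) break
    bi <- stats::pbeta(W[act, i], i, m[act] - i + 1)
    rho[act] <- pmin(rho[act], bi)
  }
  rho
}

# Index draws for the permutation null: n_permutations rows of k distinct
# positions in a pool of size n_pool, deterministic in (k, seed) only, so
# the same draws serve every gene with k guides and every alpha.
perm_index_draws <- function(n_pool, k, n_permutations, seed) {
  with_preserved_seed(seed + k, {
    t(vapply(seq_len(n_permutations),
             function(i) sample.int(n_pool, k), integer(k)))
  })
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as the
#' package's single point of FDR adjustment.
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of BH q-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Gene-level alpha-RRA test with a permutation null
#'
#' Aggregates guide-level enrichment p-values to gene scores. Guides are
#' ranked into percentiles over the full pool (controls included); a guide
#' passes the filter when its one-sided p-value is below `alpha`
#' (equivalently, its percentile is below the alpha-quantile of the pool).
#' Each gene's passing percentiles give a [rra_rho()] score; its
#' significance is the plus-one permutation p-value against a null built
#' by drawing, for each permutation, the gene's number of guides uniformly
#' without replacement from the percentile pool and applying the same
#' selection and score. Null distributions are cached per distinct guide
#' count, so the test is deterministic given the seed and independent of
#' gene order. BH q-values are appended.
#'
#' @param guide_stats a [guide_test()] result with `gene_id` attached.
#' @param alpha guide p-value threshold in (0, 1].
#' @param n_permutations number of permutations (>= 100); default 20000.
#' @param seed integer seed for the permutation draws.
#' @param genes optional character vector restricting which genes are
#'   tested (e.g. transcribed genes only); their guides still contribute
#'   to the percentile pool either way.
#' @param direction passed to [guide_percentiles()].
#' @param perm_draws optional precomputed draws from internal caching
#'   (used by [tune_alpha()]); leave `NULL`.
#' @return data frame of class `gene_results` with columns `gene_id`,
#'   `n_guides`, `guides_passing_alpha`, `rho`, `p_perm`, `q_bh`, `rank`.
#' @export
gene_rra_test <- function(guide_stats, alpha, n_permutations = 20000,
                          seed = 1, genes = NULL,
                          direction = c("low_enrichment", "high_enrichment"),
                          perm_draws = NULL) {
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha <= 1, n_permutations >= 100)
  if (is.null(guide_stats$gene_id) || all(is.na(guide_stats$gene_id)))
    stop("guide_stats must carry gene_id (run guide_test with a library)",
         call. = FALSE)
  p <- if (direction == "low_enrichment") guide_stats$p_low else
    guide_stats$p_high
  u <- guide_percentiles(guide_stats, direction)
  n_pool <- length(u)
  n_pass <- sum(p < alpha)
  u_cut <- n_pass / n_pool

  targ <- !is.na(guide_stats$gene_id)
  gene_of <- guide_stats$gene_id[targ]
  u_targ <- u[targ]
  gene_ids <- if (is.null(genes)) unique(gene_of) else genes
  absent <- setdiff(gene_ids, gene_of)
  if (length(absent)) {
    warning(length(absent), " gene(s) with no scored guides excluded: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    gene_ids <- setdiff(gene_ids, absent)
  }
  groups <- split(u_targ, factor(gene_of, levels = gene_ids))
  k_gene <- lengths(groups)
  rho_obs <- vapply(groups, function(ug) rra_rho(ug[ug <= u_cut]), numeric(1))
  n_sel <- vapply(groups, function(ug) sum(ug <= u_cut), integer(1))

  p_perm <- numeric(length(gene_ids))
  for (k in sort(unique(k_gene))) {
    draws <- if (!is.null(perm_draws) && !is.null(perm_draws[[as.character(k)]]))
      perm_draws[[as.character(k)]]
    else perm_index_draws(n_pool, k, n_permutations, seed)
    null_rho <- sort(rra_rho_rows(matrix(u[draws], nrow = nrow(draws)), u_cut))
    idx <- which(k_gene == k)
    cnt <- findInterval(rho_obs[idx], null_rho)
    p_perm[idx] <- (1 + cnt) / (nrow(draws) + 1)
  }

  out <- data.frame(gene_id = gene_ids, n_guides = as.integer(k_gene),
                    guides_passing_alpha = as.integer(n_sel),
                    rho = unname(rho_obs), p_perm = p_perm,
                    q_bh = adjust_bh(p_perm),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- order(order(out$p_perm, out$rho))
  class(out) <- c("gene_results", "data.frame")
  out
}
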