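#' Run configuration for a sorted-screen analysis
#'
#' @param alpha guide p-value threshold for the RRA filter, in (0, 1].
#' @param n_permutations permutations for the gene-level null (>= 100).
#' @param pseudocount added to normalized counts (default 0; the log fold
#'   change uses its own `lfc_pseudocount`).
#' @param rng_seed integer seed for all randomized stages.
#' @param fdr_q_cutoff q-value threshold declaring a gene significant.
#' @param positive_control_genes genes expected to be required for the
#'   phenotype (e.g. canonical pathway members), used by [tune_alpha()].
#' @param positive_control_q_max largest acceptable q for a positive
#'   control during tuning.
#' @param expression_threshold TPM-like cutoff below which a gene counts
#'   as not transcribed.
#' @param expression_filter if `TRUE` (default) non-transcribed genes'
#'   guides join the control set and those genes are excluded from
#'   gene-level testing.
#' @param calibrate,combine,lfc_pseudocount passed to [guide_test()].
#' @param direction passed to [gene_rra_test()].
#' @return validated list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.1, n_permutations = 20000,
                          pseudocount = 0, rng_seed = 1,
                          fdr_q_cutoff = 0.1,
                          positive_control_genes = character(),
                          positive_control_q_max = 0.05,
                          expression_threshold = 1,
                          expression_filter = TRUE,
                          calibrate = "control", combine = "sum",
                          lfc_pseudocount = 1,
                          direction = "low_enrichment") {
  cfg <- list(alpha = alpha, n_permutations = as.integer(n_permutations),
              pseudocount = pseudocount, rng_seed = as.integer(rng_seed),
              fdr_q_cutoff = fdr_q_cutoff,
              positive_control_genes = as.character(positive_control_genes),
              positive_control_q_max = positive_control_q_max,
              expression_threshold = expression_threshold,
              expression_filter = isTRUE(expression_filter),
              calibrate = match.arg(calibrate, c("control", "none")),
              combine = match.arg(combine, c("sum", "fisher")),
              lfc_pseudocount = lfc_pseudocount,
              direction = match.arg(direction,
                                    c("low_enrichment", "high_enrichment")))
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$n_permutations >= 100,
            cfg$pseudocount >= 0, cfg$fdr_q_cutoff > 0, cfg$fdr_q_cutoff < 1,
            cfg$positive_control_q_max > 0, cfg$positive_control_q_max < 1,
            cfg$expression_threshold >= 0, cfg$lfc_pseudocount >= 0)
  class(cfg) <- "screen_config"
  cfg
}

# Shared front half of the pipeline: controls, size factors,
# normalization, variance model, guide-level tests, tested-gene set.
screen_prepare <- function(counts, library, expression, config) {
  ctrl <- control_guides(library,
                         expression = if (config$expression_filter)
                           expression,
                         threshold = config$expression_threshold)
  factors <- control_size_factors(counts, ctrl)
  norm <- normalize_counts(counts, factors, config$pseudocount)
  input_cols <- samples_by_role(norm, "input")
  model <- fit_mean_variance(norm$counts[, input_cols, drop = FALSE])
  gs <- guide_test(norm, model, library = library, control = ctrl,
                   calibrate = config$calibrate, combine = config$combine,
                   lfc_pseudocount = config$lfc_pseudocount)
  tested <- library_genes(library)
  if (config$expression_filter && !is.null(expression)) {
    expr <- expression$expression[match(tested, expression$gene_id)]
    expr[is.na(expr)] <- 0
    tested <- tested[expr > config$expression_threshold]
  }
  list(control = ctrl, size_factors = factors, norm = norm, model = model,
       guide_stats = gs, tested_genes = tested)
}

#' Fit the sorted-screen enrichment model
#'
#' The package's central fitting function: runs control-set construction,
#' median-of-ratios normalization, input-based variance estimation,
#' guide-level bin-enrichment testing and alpha-RRA gene aggregation with
#' a permutation null, returning everything as one object.
#'
#' @param counts a [screen_counts] of raw counts.
#' @param library the matching [guide_library].
#' @param expression optional per-gene expression table (`gene_id`,
#'   `expression`); enables the expression-aware control set and gene
#'   filter.
#' @param config a [screen_config()].
#' @return object of class `sortscreen` with components `guide_stats`,
#'   `gene_results`, `control_guides`, `size_factors`, `mv_model`,
#'   `normalized`, `tested_genes`, `config`.
#' @seealso [summary.sortscreen()], [plot.sortscreen()], [tune_alpha()],
#'   [screen_ppv()]
#' @export
sortscreen <- function(counts, library, expression = NULL,
                       config = screen_config()) {
  stopifnot(inherits(counts, "screen_counts"),
            inherits(library, "guide_library"),
            inherits(config, "screen_config"))
  prep <- screen_prepare(counts, library, expression, config)
  gr <- gene_rra_test(prep$guide_stats, alpha = config$alpha,
                      n_permutations = config$n_permutations,
                      seed = config$rng_seed, genes = prep$tested_genes,
                      direction = config$direction)
  structure(list(guide_stats = prep$guide_stats, gene_results = gr,
                 control_guides = prep$control,
                 size_factors = prep$size_factors, mv_model = prep$model,
                 normalized = prep$norm, tested_genes = prep$tested_genes,
                 config = config),
            class = "sortscreen")
}

#' @export
print.sortscreen <- function(x, ...) {
  n_sig <- sum(x$gene_results$q_bh < x$config$fdr_q_cutoff)
  cat(sprintf("sortscreen fit: %d guides, %d genes tested, %d control guides\n",
              nrow(x$guide_stats), nrow(x$gene_results),
              length(x$control_guides)))
  cat(sprintf("  alpha = %g, %d permutations; %d gene(s) at q < %g\n",
              x$config$alpha, x$config$n_permutations, n_sig,
              x$config$fdr_q_cutoff))
  invisible(x)
}

#' Summarize a sorted-screen fit
#'
#' Produces the run overview: the top genes by q-value, the number of
#' significant genes at the configured cutoff, the control-set size, and
#' the histogram of per-gene guide support (how many of a gene's guides
#' pass the alpha filter).
#'
#' @param object a [sortscreen()] fit.
#' @param top_n rows in the top-gene table (default 10).
#' @param ... unused.
#' @return list of class `summary.sortscreen` with elements `top`,
#'   `n_significant`, `q_cutoff`, `guide_support` (named table over
#'   0..max guides), `control_set_size`, `n_genes_tested`.
#' @export
summary.sortscreen <- function(object, top_n = 10, ...) {
  gr <- object$gene_results[order(object$gene_results$rank), ]
  support <- table(factor(gr$guides_passing_alpha,
                          levels = 0:max(gr$n_guides)))
  out <- list(top = utils::head(gr, top_n),
              n_significant = sum(gr$q_bh < object$config$fdr_q_cutoff),
              q_cutoff = object$config$fdr_q_cutoff,
              guide_support = support,
              control_set_size = length(object$control_guides),
              n_genes_tested = nrow(gr))
  class(out) <- "summary.sortscreen"
  out
}

#' @export
print.summary.sortscreen <- function(x, ...) {
  cat(sprintf("%d gene(s) significant at q < %g (of %d tested; %d control guides)\n",
              x$n_significant, x$q_cutoff, x$n_genes_tested,
              x$control_set_size))
  cat("guides passing alpha per gene:\n")
  print(x$guide_support)
  cat("top genes:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Gene-score overview plot
#'
#' Rank-versus-score plot of the gene results: genes ordered by rank on
#' the x axis, `-log10(rho)` on the y axis, significant genes (q below
#' the configured cutoff) highlighted.
#'
#' @param x a [sortscreen()] fit.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sortscreen <- function(x, ...) {
  gr <- x$gene_results
  sig <- gr$q_bh < x$config$fdr_q_cutoff
  plot(gr$rank, -log10(gr$rho),
       col = ifelse(sig, "firebrick", "grey50"),
       pch = ifelse(sig, 19, 1), xlab = "gene rank",
       ylab = expression(-log[10](rho)), ...)
  invisible(x)
}
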