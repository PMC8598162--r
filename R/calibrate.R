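# Alpha tuning against positive controls and PPV evaluation.

#' Tune the alpha threshold against positive-control genes
#'
#' Screens a grid of alpha values for the RRA guide filter. For each
#' alpha the guide-to-gene pipeline is re-run (guide statistics and
#' permutation index draws are computed once and reused, so the report is
#' reproducible bit-for-bit given the seed). An alpha is *feasible* when
#' every designated positive-control gene keeps `q_bh` at or below
#' `positive_control_q_max`; among feasible values, `alpha_star` maximizes
#' the number of genes significant at `fdr_q_cutoff`, with ties broken
#' toward the smallest alpha. If no alpha is feasible, the value
#' minimizing the worst positive-control q is returned flagged
#' `INFEASIBLE`.
#'
#' @param counts raw [screen_counts].
#' @param library the [guide_library].
#' @param expression optional expression table.
#' @param config a [screen_config()] with non-empty
#'   `positive_control_genes`.
#' @param alpha_grid candidate alpha values in (0, 1].
#' @return list of class `alpha_tuning`: `alpha_star`, `feasible`
#'   (logical), `report` (data frame `alpha`, `n_significant`,
#'   `worst_control_q`, `feasible`), `results` (per-alpha
#'   [gene_rra_test()] tables, named by alpha).
#' @export
tune_alpha <- function(counts, library, expression = NULL, config,
                       alpha_grid = c(0.05, 0.1, 0.15, 0.2, 0.25,
                                      0.3, 0.4, 0.5)) {
  stopifnot(inherits(config, "screen_config"),
            all(alpha_grid > 0), all(alpha_grid <= 1))
  pc <- config$positive_control_genes
  if (!length(pc))
    stop("tune_alpha needs positive_control_genes in the config",
         call. = FALSE)
  missing_pc <- setdiff(pc, library_genes(library))
  if (length(missing_pc))
    stop("positive-control gene(s) absent from library: ",
         paste(missing_pc, collapse = ", "), call. = FALSE)
  prep <- screen_prepare(counts, library, expression, config)
  ks <- unique(table(prep$guide_stats$gene_id[
    !is.na(prep$guide_stats$gene_id)]))
  n_pool <- nrow(prep$guide_stats)
  draws <- lapply(as.integer(ks), function(k)
    perm_index_draws(n_pool, k, config$n_permutations, config$rng_seed))
  names(draws) <- as.character(ks)

  results <- list()
  report <- data.frame(alpha = alpha_grid, n_significant = NA_integer_,
                       worst_control_q = NA_real_, feasible = NA)
  for (i in seq_along(alpha_grid)) {
    gr <- gene_rra_test(prep$guide_stats, alpha = alpha_grid[i],
                        n_permutations = config$n_permutations,
                        seed = config$rng_seed, genes = prep$tested_genes,
                        direction = config$direction, perm_draws = draws)
    q_pc <- gr$q_bh[match(pc, gr$gene_id)]
    worst <- if (any(is.na(q_pc))) 1 else max(q_pc)
    report$n_significant[i] <- sum(gr$q_bh < config$fdr_q_cutoff)
    report$worst_control_q[i] <- worst
    report$feasible[i] <- worst <= config$positive_control_q_max
    results[[as.character(alpha_grid[i])]] <- gr
  }
  if (any(report$feasible)) {
    cand <- report[report$feasible, ]
    cand <- cand[order(-cand$n_significant, cand$alpha), ]
    alpha_star <- cand$alpha[1]
    feasible <- TRUE
  } else {
    alpha_star <- report$alpha[which.min(report$worst_control_q)]
    feasible <- FALSE
    warning("INFEASIBLE: no alpha keeps every positive control at q <= ",
            config$positive_control_q_max,
            "; returning the alpha minimizing the worst control q",
            call. = FALSE)
  }
  structure(list(alpha_star = alpha_star, feasible = feasible,
                 report = report, results = results),
            class = "alpha_tuning")
}

#' @export
print.alpha_tuning <- function(x, ...) {
  cat(sprintf("alpha tuning: alpha_star = %g%s\n", x$alpha_star,
              if (x$feasible) "" else " (INFEASIBLE)"))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Positive-control quality control table
#'
#' One row per designated positive-control gene with its q-value and
#' guide support, sorted by q; the run passes when every control is at or
#' below the threshold.
#'
#' @param gene_results a [gene_rra_test()] table (or `sortscreen` fit).
#' @param positive_controls character vector of control gene ids.
#' @param q_max pass threshold on `q_bh` (default 0.05).
#' @return data frame (`gene_id`, `q_bh`, `guides_passing_alpha`,
#'   `pass`), with attribute `pass` summarizing the run (`TRUE` only if
#'   every control passes).
#' @export
positive_control_qc <- function(gene_results, positive_controls,
                                q_max = 0.05) {
  if (inherits(gene_results, "sortscreen"))
    gene_results <- gene_results$gene_results
  i <- match(positive_controls, gene_results$gene_id)
  out <- data.frame(gene_id = positive_controls,
                    q_bh = gene_results$q_bh[i],
                    guides_passing_alpha =
                      gene_results$guides_passing_alpha[i],
                    stringsAsFactors = FALSE)
  out$q_bh[is.na(out$q_bh)] <- 1
  out$guides_passing_alpha[is.na(out$guides_passing_alpha)] <- 0L
  out$pass <- out$q_bh <= q_max
  out <- out[order(out$q_bh), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$pass)
  out
}

#' Positive predictive value of the significant gene set
#'
#' In `simulation_truth` mode, true positives are significant genes
#' planted as hits; in `expression_filter` mode (the operational
#' definition for real screens), false positives are significant genes
#' that are not transcribed — guides against silent genes cannot produce
#' a knockout phenotype, so their significance must be noise.
#'
#' @param gene_results a [gene_rra_test()] table (or `sortscreen` fit).
#' @param truth the simulation truth `genes` table (needs `gene_id`,
#'   `is_hit`) for `simulation_truth` mode.
#' @param expression expression table for `expression_filter` mode.
#' @param q_cutoff significance threshold on `q_bh` (default 0.05).
#' @param mode `"simulation_truth"` or `"expression_filter"`.
#' @param expression_threshold cutoff separating transcribed genes
#'   (default 1).
#' @return list with `ppv` (`NA` when no gene is significant), `tp`,
#'   `fp`, `n_significant`.
#' @export
screen_ppv <- function(gene_results, truth = NULL, expression = NULL,
                       q_cutoff = 0.05,
                       mode = c("simulation_truth", "expression_filter"),
                       expression_threshold = 1) {
  mode <- match.arg(mode)
  if (inherits(gene_results, "sortscreen"))
    gene_results <- gene_results$gene_results
  sig <- gene_results$gene_id[gene_results$q_bh < q_cutoff]
  if (!length(sig))
    return(list(ppv = NA_real_, tp = 0L, fp = 0L, n_significant = 0L))
  if (mode == "simulation_truth") {
    if (is.null(truth)) stop("simulation_truth mode needs `truth`",
                             call. = FALSE)
    is_hit <- truth$is_hit[match(sig, truth$gene_id)]
    is_hit[is.na(is_hit)] <- FALSE
    tp <- sum(is_hit)
    fp <- sum(!is_hit)
  } else {
    if (is.null(expression)) stop("expression_filter mode needs `expression`",
                                  call. = FALSE)
    expr <- expression$expression[match(sig, expression$gene_id)]
    expr[is.na(expr)] <- 0
    fp <- sum(expr <= expression_threshold)
    tp <- length(sig) - fp
  }
  list(ppv = tp / (tp + fp), tp = as.integer(tp), fp = as.integer(fp),
       n_significant = length(sig))
}
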