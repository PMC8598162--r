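# Synthetic sorted-bin screen generator with known ground truth.

#' Simulation parameters for a synthetic sorted screen
#'
#' Defaults describe a desk-scale version of a genome-wide knockout screen
#' read out by quantile sorting into phenotype-high and phenotype-low bins:
#' four guides per gene plus non-targeting controls, single-integration
#' infection (one guide per cell, as under low MOI), heterogeneous guide
#' efficacy with a fraction of inactive ("dud") guides, two sorted
#' replicates, and multinomial sequencing-depth sampling.
#'
#' @param n_genes number of targeted genes (default 2000).
#' @param guides_per_gene guides per gene (default 4).
#' @param n_ntc non-targeting control guides (default 100).
#' @param frac_nonexpressed fraction of genes not transcribed in the
#'   screened line (default 0.4); their knockouts are phenotypically null.
#' @param hit_fraction fraction of expressed genes planted as regulators
#'   (default 0.05).
#' @param effect_size mean shift of the log-phenotype of a fully edited
#'   cell, in phenotype-SD units (default 2).
#' @param efficacy_shape `c(a, b)` Beta shape parameters for per-guide
#'   editing efficacy (default `c(5, 1)`).
#' @param dud_fraction fraction of targeting guides forced to efficacy 0
#'   (default 0.25).
#' @param sort_fraction_q fraction of cells gated into each bin, in
#'   (0, 0.5) (default 0.15).
#' @param n_cells sorted cells per replicate (default 2e6).
#' @param depth_per_sample sequencing reads per sample (default 5e5).
#' @param n_replicates independent screen replicates (default 2).
#' @param abundance_sigma log-normal SD of guide representation in the
#'   pool (default 0.3).
#' @param expression_threshold TPM-like cutoff separating transcribed from
#'   silent genes (default 1).
#' @param artifact_fraction fraction of non-expressed genes given a
#'   spurious gene-level sorting artifact (jackpot noise emulating e.g.
#'   cutting-toxicity effects); default 0.
#' @param artifact_effect phenotype shift (SD units) of artifact genes;
#'   default 0.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000, guides_per_gene = 4, n_ntc = 100,
                       frac_nonexpressed = 0.4, hit_fraction = 0.05,
                       effect_size = 2, efficacy_shape = c(5, 1),
                       dud_fraction = 0.25, sort_fraction_q = 0.15,
                       n_cells = 2e6, depth_per_sample = 5e5,
                       n_replicates = 2, abundance_sigma = 0.3,
                       expression_threshold = 1,
                       artifact_fraction = 0, artifact_effect = 0,
                       seed = 17) {
  p <- list(n_genes = as.integer(n_genes),
            guides_per_gene = as.integer(guides_per_gene),
            n_ntc = as.integer(n_ntc),
            frac_nonexpressed = frac_nonexpressed,
            hit_fraction = hit_fraction, effect_size = effect_size,
            efficacy_shape = efficacy_shape, dud_fraction = dud_fraction,
            sort_fraction_q = sort_fraction_q, n_cells = as.integer(n_cells),
            depth_per_sample = as.integer(depth_per_sample),
            n_replicates = as.integer(n_replicates),
            abundance_sigma = abundance_sigma,
            expression_threshold = expression_threshold,
            artifact_fraction = artifact_fraction,
            artifact_effect = artifact_effect, seed = as.integer(seed))
  stopifnot(p$n_genes >= 1, p$guides_per_gene >= 1, p$n_ntc >= 0,
            p$frac_nonexpressed >= 0, p$frac_nonexpressed <= 1,
            p$hit_fraction >= 0, p$hit_fraction <= 1, p$effect_size >= 0,
            length(p$efficacy_shape) == 2, all(p$efficacy_shape > 0),
            p$dud_fraction >= 0, p$dud_fraction <= 1,
            p$sort_fraction_q > 0, p$sort_fraction_q < 0.5,
            p$n_cells >= 1, p$depth_per_sample >= 1, p$n_replicates >= 1,
            p$abundance_sigma >= 0, p$expression_threshold >= 0,
            p$artifact_fraction >= 0, p$artifact_fraction <= 1)
  class(p) <- "sim_params"
  p
}

#' Simulate a guide library, expression table and ground truth
#'
#' Generates gene and guide identifiers, flags a fraction of genes as not
#' transcribed (expression 0; others drawn log-normally above the
#' expression threshold), plants regulator genes among the expressed ones,
#' draws per-guide efficacies from a Beta distribution with a fraction of
#' dud guides set to 0, and optionally marks non-expressed genes with a
#' gene-level sorting artifact. Fully determined by `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `library` (a [guide_library]), `expression`
#'   (data frame `gene_id`, `expression`) and `truth` (list of data frames
#'   `genes` — `gene_id`, `expressed`, `is_hit`, `effect_size`,
#'   `is_artifact`, `artifact_effect` — and `guides` — `guide_id`,
#'   `gene_id`, `efficacy`).
#' @export
simulate_guide_library <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_preserved_seed(p$seed, {
    genes <- sprintf("gene%04d", seq_len(p$n_genes))
    n_off <- floor(p$frac_nonexpressed * p$n_genes)
    off <- sample(genes, n_off)
    expressed <- !(genes %in% off)
    expr <- ifelse(expressed,
                   p$expression_threshold +
                     stats::rlnorm(p$n_genes, meanlog = 3, sdlog = 1),
                   0)
    n_hits <- floor(p$hit_fraction * sum(expressed))
    if (p$hit_fraction > 0 && n_hits < 1)
      stop("hit_fraction too small: fewer than one hit among ",
           sum(expressed), " expressed genes", call. = FALSE)
    hits <- if (n_hits > 0) sample(genes[expressed], n_hits) else character()
    n_art <- floor(p$artifact_fraction * n_off)
    artifacts <- if (n_art > 0) sample(off, n_art) else character()

    guide_gene <- rep(genes, each = p$guides_per_gene)
    guide_ids <- paste0(guide_gene, "_g",
                        rep(seq_len(p$guides_per_gene), times = p$n_genes))
    ntc_ids <- if (p$n_ntc > 0) sprintf("ntc%04d", seq_len(p$n_ntc)) else
      character()
    lib <- guide_library(c(guide_ids, ntc_ids),
                         c(guide_gene, rep(NA_character_, p$n_ntc)))

    n_targ <- length(guide_ids)
    eff <- stats::rbeta(n_targ, p$efficacy_shape[1], p$efficacy_shape[2])
    n_dud <- floor(p$dud_fraction * n_targ)
    if (n_dud > 0) eff[sample.int(n_targ, n_dud)] <- 0

    truth_genes <- data.frame(
      gene_id = genes, expressed = expressed, is_hit = genes %in% hits,
      effect_size = ifelse(genes %in% hits, p$effect_size, 0),
      is_artifact = genes %in% artifacts,
      artifact_effect = ifelse(genes %in% artifacts, p$artifact_effect, 0),
      stringsAsFactors = FALSE)
    truth_guides <- data.frame(guide_id = guide_ids, gene_id = guide_gene,
                               efficacy = eff, stringsAsFactors = FALSE)
    list(library = lib,
         expression = data.frame(gene_id = genes, expression = expr,
                                 stringsAsFactors = FALSE),
         truth = list(genes = truth_genes, guides = truth_guides))
  })
}

#' Simulate sorted-bin screen counts
#'
#' For each replicate: (1) a guide abundance vector is drawn log-normally
#' and normalized; (2) each of `n_cells` cells carries one guide (single
#' integration), is functionally edited with probability equal to that
#' guide's efficacy (never for NTCs), and draws a log-phenotype from
#' `Normal(-effect * edited, 1)` where `effect` is the gene's planted
#' effect plus any artifact effect; (3) the empirical `q` and `1 - q`
#' phenotype quantiles gate the low and high bins; (4) the input sample is
#' a multinomial draw of `depth_per_sample` reads from the abundance
#' vector, and each bin a multinomial draw from its within-bin guide
#' frequencies. Deterministic given `seed`.
#'
#' @param library a [guide_library] from [simulate_guide_library()].
#' @param truth matching ground truth.
#' @param params the [sim_params()].
#' @param seed integer seed; defaults to `params$seed + 1` so that library
#'   and screen draws are decoupled but still reproducible from the
#'   parameter set alone.
#' @return a [screen_counts] with samples `input`/`bin_high`/`bin_low`
#'   for each replicate.
#' @export
simulate_sorted_screen <- function(library, truth, params,
                                   seed = params$seed + 1L) {
  stopifnot(inherits(library, "guide_library"), inherits(params, "sim_params"))
  p <- params
  n_guides <- nrow(library)
  k_bin <- max(1L, floor(p$sort_fraction_q * p$n_cells))
  if (p$n_cells * p$sort_fraction_q < 10 * n_guides)
    warning("sorted-bin coverage below ~10 cells per guide; increase ",
            "n_cells or the bin fraction", call. = FALSE)
  gene_effect <- truth$genes$effect_size + truth$genes$artifact_effect
  names(gene_effect) <- truth$genes$gene_id
  eff_shift <- ifelse(is.na(library$gene_id), 0,
                      gene_effect[library$gene_id])
  efficacy <- truth$guides$efficacy[match(library$guide_id,
                                          truth$guides$guide_id)]
  efficacy[is.na(efficacy)] <- 0  # NTCs: never functionally edited

  cols <- list()
  info <- list()
  with_preserved_seed(seed, {
    for (r in seq_len(p$n_replicates)) {
      a <- stats::rlnorm(n_guides, 0, p$abundance_sigma)
      a <- a / sum(a)
      n_cell_guide <- as.vector(stats::rmultinom(1, p$n_cells, a))
      edited <- stats::rbinom(n_guides, n_cell_guide, efficacy)
      cell_guide <- rep.int(seq_len(n_guides), n_cell_guide)
      edit_flag <- rep.int(rep(c(TRUE, FALSE), n_guides),
                           as.vector(rbind(edited, n_cell_guide - edited)))
      phen <- stats::rnorm(p$n_cells) -
        eff_shift[cell_guide] * edit_flag
      thr_lo <- sort(phen, partial = k_bin)[k_bin]
      hi_at <- p$n_cells - k_bin + 1L
      thr_hi <- sort(phen, partial = hi_at)[hi_at]
      low_cells <- tabulate(cell_guide[phen <= thr_lo], nbins = n_guides)
      high_cells <- tabulate(cell_guide[phen >= thr_hi], nbins = n_guides)
      cols[[paste0("input_rep", r)]] <-
        as.vector(stats::rmultinom(1, p$depth_per_sample, a))
      cols[[paste0("high_rep", r)]] <-
        as.vector(stats::rmultinom(1, p$depth_per_sample, high_cells))
      cols[[paste0("low_rep", r)]] <-
        as.vector(stats::rmultinom(1, p$depth_per_sample, low_cells))
      info[[r]] <- data.frame(
        sample = paste0(c("input_rep", "high_rep", "low_rep"), r),
        role = c("input", "bin_high", "bin_low"),
        replicate = paste0("rep", r), stringsAsFactors = FALSE)
    }
  })
  m <- do.call(cbind, cols)
  rownames(m) <- library$guide_id
  screen_counts(m, do.call(rbind, info))
}

#' Write a complete simulated fixture to disk
#'
#' Serializes library, counts, expression, truth tables and a
#' `manifest.yaml` recording the parameters and seed, in the package's
#' text formats. Re-running the simulation from the manifest reproduces
#' the files byte-identically.
#'
#' @param sim a [simulate_guide_library()] result.
#' @param counts the matching [simulate_sorted_screen()] counts.
#' @param params the [sim_params()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_fixture <- function(sim, counts, params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_guide_library(sim$library, file.path(out_dir, "library.tsv"))
  write_count_matrix(counts, sim$library, file.path(out_dir, "counts.tsv"))
  write_expression_table(sim$expression, file.path(out_dir, "expression.tsv"))
  utils::write.table(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$guides, file.path(out_dir, "truth_guides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(params), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Rebuild simulation parameters from a fixture manifest
#' @param path path to a `manifest.yaml` written by [write_sim_fixture()].
#' @return a [sim_params()] object.
#' @export
read_sim_manifest <- function(path) {
  do.call(sim_params, yaml::read_yaml(path))
}
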