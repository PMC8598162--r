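# Shared fixtures, built in code.

# A 3-gene toy library: geneA/geneB expressed, geneC silent, plus NTCs.
toy_library <- function(n_ntc = 2) {
  genes <- c("geneA", "geneB", "geneC")
  guide_library(
    c(paste0(rep(genes, each = 2), "_g", 1:2),
      if (n_ntc > 0) paste0("ntc", seq_len(n_ntc))),
    c(rep(genes, each = 2), rep(NA, n_ntc)))
}

toy_expression <- function() {
  data.frame(gene_id = c("geneA", "geneB", "geneC"),
             expression = c(50, 12, 0), stringsAsFactors = FALSE)
}

# Raw counts for the toy library: 1 input + 1 high/low pair.
toy_counts <- function(lib = toy_library(), seed = 7) {
  n <- nrow(lib)
  m <- matrix(withr_seed_rpois(seed, n * 4L, 100), nrow = n,
              dimnames = list(lib$guide_id,
                              c("input_rep1", "input_rep2",
                                "high_rep1", "low_rep1")))
  screen_counts(m, data.frame(
    sample = colnames(m),
    role = c("input", "input", "bin_high", "bin_low"),
    replicate = c("rep1", "rep2", "rep1", "rep1"),
    stringsAsFactors = FALSE))
}

withr_seed_rpois <- function(seed, n, lambda) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rpois(n, lambda)
}

# Small fast simulation preset for unit tests.
small_params <- function(...) {
  sim_params(n_genes = 60, n_ntc = 20, n_cells = 6e4,
             depth_per_sample = 3e4, ...)
}

# Independent brute-force oracle for the beta order-statistic CDF:
# P(Beta(i, m - i + 1) <= u) computed by explicit binomial summation,
# i.e. the probability that at least i of m uniforms fall below u.
beta_cdf_binom_sum <- function(u, i, m) {
  j <- i:m
  sum(choose(m, j) * u^j * (1 - u)^(m - j))
}

rra_rho_oracle <- function(u_selected) {
  m <- length(u_selected)
  if (m == 0L) return(1)
  u <- sort(u_selected)
  min(vapply(seq_len(m), function(i) beta_cdf_binom_sum(u[i], i, m),
             numeric(1)))
}
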