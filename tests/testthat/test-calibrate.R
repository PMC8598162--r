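# Shared small simulated screen with planted hits, fit once per file.
sim_env <- local({
  p <- sim_params(n_genes = 300, n_ntc = 60, n_cells = 3e5,
                  depth_per_sample = 1.5e5, seed = 77)
  sim <- simulate_guide_library(p)
  cnt <- simulate_sorted_screen(sim$library, sim$truth, p)
  list(p = p, sim = sim, cnt = cnt)
})

strong_hits <- function(sim, n) {
  tg <- sim$truth$genes
  tu <- sim$truth$guides
  strong <- tapply(tu$efficacy, tu$gene_id, function(e) sum(e > 0.5))
  head(tg$gene_id[tg$is_hit & strong[tg$gene_id] >= 3], n)
}

test_that("a one-point alpha grid returns that alpha with a one-row report", {
  s <- sim_env
  pc <- strong_hits(s$sim, 2)
  cfg <- screen_config(n_permutations = 2000, rng_seed = 1,
                       positive_control_genes = pc,
                       fdr_q_cutoff = 0.05)
  tuned <- tune_alpha(s$cnt, s$sim$library, s$sim$expression, cfg,
                      alpha_grid = 0.1)
  expect_equal(tuned$alpha_star, 0.1)
  expect_equal(nrow(tuned$report), 1L)
  expect_true(tuned$feasible)
})

test_that("tuning is reproducible bit-for-bit given the seed", {
  s <- sim_env
  cfg <- screen_config(n_permutations = 1000, rng_seed = 3,
                       positive_control_genes = strong_hits(s$sim, 2))
  t1 <- tune_alpha(s$cnt, s$sim$library, s$sim$expression, cfg,
                   alpha_grid = c(0.05, 0.2))
  t2 <- tune_alpha(s$cnt, s$sim$library, s$sim$expression, cfg,
                   alpha_grid = c(0.05, 0.2))
  expect_identical(t1$report, t2$report)
})

test_that("a positive control absent from the library is a named error", {
  s <- sim_env
  cfg <- screen_config(positive_control_genes = c("gene0001", "noSuchGene"))
  expect_error(tune_alpha(s$cnt, s$sim$library, s$sim$expression, cfg),
               "noSuchGene")
  expect_error(tune_alpha(s$cnt, s$sim$library, s$sim$expression,
                          screen_config()),
               "positive_control_genes")
})

test_that("positive-control QC reports one sorted row per control", {
  gr <- data.frame(gene_id = c("a", "b", "c"),
                   q_bh = c(0.2, 0.001, 0.04),
                   guides_passing_alpha = c(0L, 4L, 2L))
  qc <- positive_control_qc(gr, c("a", "b", "c", "zz"), q_max = 0.05)
  expect_equal(nrow(qc), 4L)
  expect_equal(qc$gene_id, c("b", "c", "a", "zz"))
  expect_equal(qc$pass, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(attr(qc, "pass"))
  # a control with no effective guides fails with zero support
  expect_equal(qc$guides_passing_alpha[qc$gene_id == "zz"], 0L)
  qc2 <- positive_control_qc(gr[2:3, ], c("b", "c"), q_max = 0.05)
  expect_true(attr(qc2, "pass"))
})

test_that("PPV handles pure-hit and empty significant sets", {
  truth <- data.frame(gene_id = c("a", "b", "c"),
                      is_hit = c(TRUE, TRUE, FALSE))
  gr <- data.frame(gene_id = c("a", "b", "c"),
                   q_bh = c(0.001, 0.01, 0.9))
  res <- screen_ppv(gr, truth = truth, q_cutoff = 0.05)
  expect_equal(res$ppv, 1)
  expect_equal(res$tp, 2L)
  gr$q_bh <- c(0.5, 0.6, 0.9)
  res0 <- screen_ppv(gr, truth = truth, q_cutoff = 0.05)
  expect_true(is.na(res0$ppv))
  expect_equal(res0$n_significant, 0L)
  # expression-filter mode: significant silent genes are the FPs
  expr <- data.frame(gene_id = c("a", "b", "c"),
                     expression = c(30, 0, 40))
  gr2 <- data.frame(gene_id = c("a", "b", "c"),
                    q_bh = c(0.001, 0.01, 0.9))
  res2 <- screen_ppv(gr2, expression = expr, q_cutoff = 0.05,
                     mode = "expression_filter")
  expect_equal(res2$fp, 1L)
  expect_equal(res2$ppv, 0.5)
})

test_that("planted-hit positive controls pass QC on a simulated screen", {
  s <- sim_env
  fit <- sortscreen(s$cnt, s$sim$library, s$sim$expression,
                    screen_config(n_permutations = 5000, rng_seed = 2))
  tg <- s$sim$truth$genes
  tu <- s$sim$truth$guides
  strong <- tapply(tu$efficacy, tu$gene_id, function(e) sum(e > 0.5))
  pc <- head(tg$gene_id[tg$is_hit & strong[tg$gene_id] >= 3], 3)
  qc <- positive_control_qc(fit, pc, q_max = 0.05)
  expect_true(attr(qc, "pass"))
  expect_true(all(qc$guides_passing_alpha >= 1))
})
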