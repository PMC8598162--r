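test_that("library simulation has the right shape and is seed-deterministic", {
  p <- sim_params(n_genes = 10, guides_per_gene = 4, n_ntc = 5,
                  hit_fraction = 0.2, n_cells = 1e4,
                  depth_per_sample = 5e3, seed = 2)
  sim <- simulate_guide_library(p)
  expect_equal(nrow(sim$library), 45L)           # 10*4 + 5
  expect_equal(n_ntc(sim$library), 5L)
  expect_equal(nrow(sim$truth$genes), 10L)
  expect_equal(sum(sim$expression$expression == 0),
               floor(0.4 * 10))
  sim2 <- simulate_guide_library(p)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$expression, sim2$expression)
})

test_that("hit_fraction = 0 plants no hits; tiny hit_fraction errors", {
  p <- small_params(hit_fraction = 0, seed = 5)
  sim <- simulate_guide_library(p)
  expect_equal(sum(sim$truth$genes$is_hit), 0L)
  expect_true(all(sim$truth$genes$effect_size == 0))
  p2 <- small_params(hit_fraction = 0.001, seed = 5)
  expect_error(simulate_guide_library(p2), "fewer than one hit")
})

test_that("non-expressed genes never carry planted effects", {
  sim <- simulate_guide_library(small_params(seed = 6))
  tg <- sim$truth$genes
  expect_true(all(tg$effect_size[!tg$expressed] == 0))
  expect_true(all(tg$expressed[tg$is_hit]))
})

test_that("sample column sums equal the sequencing depth exactly", {
  p <- small_params(seed = 7)
  sim <- simulate_guide_library(p)
  cnt <- simulate_sorted_screen(sim$library, sim$truth, p)
  expect_true(all(colSums(cnt$counts) == p$depth_per_sample))
  expect_equal(ncol(cnt$counts), 3L * p$n_replicates)
  cnt2 <- simulate_sorted_screen(sim$library, sim$truth, p)
  expect_identical(cnt$counts, cnt2$counts)
})

test_that("a saturating effect inflates low-bin frequency by ~1/q", {
  # one planted hit with near-certain editing and a huge phenotype shift:
  # all its cells sort into the low bin, so its low-bin frequency rises
  # by a factor of about 1/q relative to the input.
  p <- sim_params(n_genes = 25, n_ntc = 5, hit_fraction = 0.05,
                  frac_nonexpressed = 0.2, effect_size = 50,
                  efficacy_shape = c(500, 1), dud_fraction = 0,
                  sort_fraction_q = 0.1, n_cells = 2e5,
                  depth_per_sample = 1e5, n_replicates = 4,
                  abundance_sigma = 0.1, seed = 31)
  sim <- simulate_guide_library(p)
  cnt <- simulate_sorted_screen(sim$library, sim$truth, p)
  hit <- sim$truth$genes$gene_id[sim$truth$genes$is_hit]
  expect_length(hit, 1L)
  gidx <- which(sim$library$gene_id %in% hit)
  lo <- cnt$samples$sample[cnt$samples$role == "bin_low"]
  inp <- cnt$samples$sample[cnt$samples$role == "input"]
  f_lo <- mean(cnt$counts[gidx, lo] / p$depth_per_sample)
  f_in <- mean(cnt$counts[gidx, inp] / p$depth_per_sample)
  expect_gt(f_lo / f_in, 1 / p$sort_fraction_q * 0.85)
  expect_lt(f_lo / f_in, 1 / p$sort_fraction_q * 1.15)
})

test_that("under the null, low/high log-ratios center on zero", {
  lr <- numeric(0)
  for (s in 1:5) {
    p <- small_params(hit_fraction = 0, abundance_sigma = 0.1,
                      seed = 40 + s)
    sim <- simulate_guide_library(p)
    cnt <- simulate_sorted_screen(sim$library, sim$truth, p)
    lo <- rowSums(cnt$counts[, cnt$samples$role == "bin_low"])
    hi <- rowSums(cnt$counts[, cnt$samples$role == "bin_high"])
    lr <- c(lr, log((lo + 1) / (hi + 1)))
  }
  expect_lt(abs(mean(lr)), 0.02)
})

test_that("NTC guides are indistinguishable from neutral targeting guides", {
  p <- sim_params(n_genes = 200, n_ntc = 200, hit_fraction = 0,
                  n_cells = 4e5, depth_per_sample = 2e5, seed = 50)
  sim <- simulate_guide_library(p)
  cnt <- simulate_sorted_screen(sim$library, sim$truth, p)
  lo <- rowSums(cnt$counts[, cnt$samples$role == "bin_low"])
  hi <- rowSums(cnt$counts[, cnt$samples$role == "bin_high"])
  lfc <- log2((hi + 1) / (lo + 1))
  is_ntc <- sim$library$role == "non_targeting"
  ks <- suppressWarnings(ks.test(lfc[is_ntc], lfc[!is_ntc]))
  expect_gt(ks$p.value, 0.01)
})

test_that("low sorted coverage triggers a warning", {
  p <- sim_params(n_genes = 100, n_ntc = 0, n_cells = 2000,
                  depth_per_sample = 1e4, seed = 3)
  sim <- simulate_guide_library(p)
  expect_warning(simulate_sorted_screen(sim$library, sim$truth, p),
                 "coverage")
})

test_that("fixtures regenerate byte-identically from their manifest", {
  p <- sim_params(n_genes = 12, n_ntc = 4, hit_fraction = 0.25,
                  n_cells = 1e4, depth_per_sample = 5e3, seed = 9)
  sim <- simulate_guide_library(p)
  cnt <- simulate_sorted_screen(sim$library, sim$truth, p)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_fixture(sim, cnt, p, d1)
  p2 <- read_sim_manifest(file.path(d1, "manifest.yaml"))
  sim2 <- simulate_guide_library(p2)
  cnt2 <- simulate_sorted_screen(sim2$library, sim2$truth, p2)
  write_sim_fixture(sim2, cnt2, p2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  truth <- read.table(file.path(d1, "truth_genes.tsv"), header = TRUE)
  expect_equal(nrow(truth), p$n_genes)
})
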