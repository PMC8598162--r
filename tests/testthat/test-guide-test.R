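poisson_model <- function()
  structure(list(a = -Inf, b = 0, n_points = 0L, poisson = TRUE,
                 eps = 1e-8), class = "mean_variance_model")

one_pair_counts <- function(high, low) {
  n <- length(high)
  m <- cbind(high_rep1 = high, low_rep1 = low)
  rownames(m) <- paste0("g", seq_len(n))
  screen_counts(m, data.frame(sample = colnames(m),
                              role = c("bin_high", "bin_low"),
                              replicate = "rep1"), normalized = TRUE)
}

test_that("with a Poisson model the low-bin p equals the closed-form tail", {
  gs <- guide_test(one_pair_counts(50, 150), poisson_model(),
                   calibrate = "none")
  # continuity-corrected upper tail at mu = (50+150)/2 = 100, obs = 150:
  # interpolated survival at 149.5 = P(X >= 150) - 0.5 P(X = 150)
  expected <- ppois(149, 100, lower.tail = FALSE) - 0.5 * dpois(150, 100)
  expect_equal(gs$p_low, expected, tolerance = 1e-12)
  expect_equal(gs$p_high,
               ppois(49, 100, lower.tail = FALSE) - 0.5 * dpois(50, 100),
               tolerance = 1e-12)
})

test_that("p_low is monotone decreasing in the observed low count", {
  obs <- seq(80, 180, by = 5)
  p <- vapply(obs, function(o)
    guide_test(one_pair_counts(200 - o, o), poisson_model(),
               calibrate = "none")$p_low, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("equal bins give zero LFC and a two-sided p of ~1", {
  gs <- guide_test(one_pair_counts(c(100, 40), c(100, 40)),
                   poisson_model(), calibrate = "none")
  expect_equal(gs$lfc_hi_over_low, c(0, 0))
  expect_true(all(gs$p_twosided > 0.95))
})

test_that("all-zero guides are flagged with p = 1", {
  gs <- guide_test(one_pair_counts(c(0, 50), c(0, 50)), poisson_model(),
                   calibrate = "none")
  expect_true(gs$zero_flag[1])
  expect_equal(gs$p_low[1], 1)
  expect_equal(gs$p_high[1], 1)
  expect_false(gs$zero_flag[2])
})

test_that("control calibration is strictly monotone and rank-preserving", {
  set.seed(5)
  p_model <- sort(runif(500))
  ref <- runif(300)
  cal <- sortscreen:::calibrate_to_controls(p_model, ref)
  expect_true(all(diff(cal) > 0))
  expect_true(all(cal > 0 & cal <= 1))
  # values inside the reference range land near the reference ECDF
  mid <- p_model > quantile(ref, 0.1) & p_model < quantile(ref, 0.9)
  ecdf_ref <- ecdf(ref)(p_model[mid])
  expect_lt(max(abs(cal[mid] - ecdf_ref)), 0.05)
  # more extreme than every control: still resolved, below 1/(n+1)
  tiny <- sortscreen:::calibrate_to_controls(c(1e-10, 1e-8), ref)
  expect_lt(tiny[1], tiny[2])
  expect_lt(tiny[2], 1 / 301)
})

test_that("replicate handling: Fisher combination agrees with sum in direction", {
  set.seed(6)
  n <- 200
  m <- cbind(high_rep1 = rpois(n, 100), low_rep1 = rpois(n, 100),
             high_rep2 = rpois(n, 100), low_rep2 = rpois(n, 100))
  m[1, c(2, 4)] <- 300  # one guide strongly low-enriched in both replicates
  rownames(m) <- paste0("g", seq_len(n))
  cnt <- screen_counts(m, data.frame(
    sample = colnames(m),
    role = c("bin_high", "bin_low", "bin_high", "bin_low"),
    replicate = c("rep1", "rep1", "rep2", "rep2")), normalized = TRUE)
  gs_sum <- guide_test(cnt, poisson_model(), calibrate = "none")
  gs_fis <- guide_test(cnt, poisson_model(), calibrate = "none",
                       combine = "fisher")
  expect_lt(gs_sum$p_low[1], 1e-6)
  expect_lt(gs_fis$p_low[1], 1e-6)
  expect_equal(which.min(gs_sum$p_low), 1L)
  expect_equal(which.min(gs_fis$p_low), 1L)
})

test_that("a bin_high/bin_low pair is required", {
  m <- cbind(input_rep1 = rpois(10, 50))
  rownames(m) <- paste0("g", 1:10)
  cnt <- screen_counts(m, data.frame(sample = "input_rep1", role = "input",
                                     replicate = "rep1"), normalized = TRUE)
  expect_error(guide_test(cnt, poisson_model(), calibrate = "none"),
               "bin_high/bin_low pair")
})
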