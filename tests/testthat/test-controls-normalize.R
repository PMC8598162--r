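test_that("control set unions NTCs with guides of non-transcribed genes", {
  lib <- guide_library(
    c(paste0("off_g", 1:4), paste0("on_g", 1:4), "n1"),
    c(rep("geneOff", 4), rep("geneOn", 4), NA))
  expr <- data.frame(gene_id = c("geneOff", "geneOn"), expression = c(0, 50))
  ctrl <- control_guides(lib, expr, threshold = 1)
  expect_setequal(ctrl, c(paste0("off_g", 1:4), "n1"))
  expect_length(ctrl, 5L)
})

test_that("an empty control set is a hard error", {
  lib <- guide_library(c("g1", "g2"), c("A", "B"))
  expr <- data.frame(gene_id = c("A", "B"), expression = c(10, 20))
  expect_error(control_guides(lib, expr), "empty control set")
})

test_that("control set is monotone in the expression threshold", {
  set.seed(3)
  genes <- paste0("g", 1:40)
  lib <- guide_library(paste0(rep(genes, each = 2), "_", 1:2),
                       rep(genes, each = 2))
  expr <- data.frame(gene_id = genes, expression = rexp(40, 1 / 5))
  thresholds <- sort(runif(8, 0, 20))
  sets <- lapply(thresholds, function(t) control_guides(lib, expr, t))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("genes absent from the expression table join the control set", {
  lib <- guide_library(c("a1", "b1", "n1"), c("A", "B", NA))
  expr <- data.frame(gene_id = "A", expression = 50)
  expect_message(ctrl <- control_guides(lib, expr), "not transcribed")
  expect_setequal(ctrl, c("b1", "n1"))
})

test_that("size factors reproduce hand-computed medians of ratios", {
  m <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("A", "B")))
  f <- control_size_factors(m, paste0("g", 1:4))
  expect_equal(unname(f["B"] / f["A"]), 2)
  norm <- normalize_counts(m, f)
  expect_equal(norm[, "A"], norm[, "B"])
})

test_that("identical samples give equal factors; scaling is exactly equivariant", {
  m <- matrix(rep(c(5, 50, 500), 3), ncol = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  f0 <- control_size_factors(m, paste0("g", 1:3))
  expect_equal(unname(f0), rep(f0[[1]], 3))
  n0 <- normalize_counts(m, f0)
  expect_equal(n0[, 1], n0[, 2])
  m2 <- m
  m2[, 2] <- m[, 2] * 7
  f <- control_size_factors(m2, paste0("g", 1:3))
  expect_equal(f[2], f0[2] * 7)
  expect_equal(f[-2], f0[-2])
  norm <- normalize_counts(m2, f)
  expect_equal(norm, n0)
})

test_that("non-control spikes cannot move a sample's size factor", {
  set.seed(11)
  m <- matrix(rpois(60, 100), ncol = 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  ctrl <- paste0("g", 1:10)
  f0 <- control_size_factors(m, ctrl)
  m_spiked <- m
  m_spiked["g15", 2] <- 1e7
  expect_equal(control_size_factors(m_spiked, ctrl), f0)
})

test_that("normalization with unit factors is the identity; pseudocount adds", {
  cnt <- toy_counts()
  f <- setNames(rep(1, 4), colnames(cnt$counts))
  norm <- normalize_counts(cnt, f)
  expect_true(norm$normalized)
  expect_equal(norm$counts, cnt$counts + 0)
  norm2 <- normalize_counts(cnt, f, pseudocount = 0.5)
  expect_equal(norm2$counts, cnt$counts + 0.5)
})

test_that("zero-only control guides in some sample are excluded, not imputed", {
  m <- matrix(c(0, 10, 20, 5, 12, 22), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  f <- control_size_factors(m, paste0("g", 1:3))
  libsize <- colSums(m[2:3, ])
  rel <- sweep(m[2:3, ], 2, libsize, "/")
  ref <- exp(rowMeans(log(rel)))
  expect_equal(unname(f),
               unname(libsize * apply(rel / ref, 2, median) / 1e6))
  m0 <- matrix(c(0, 5, 3, 0), ncol = 2,
               dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(control_size_factors(m0, c("g1", "g2")), "pseudocount")
})
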