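# Integrative DEG statistic: T/M, permutation nulls, empirical p-values,
# Stouffer combination and the dual gate.

test_that("T and M match the textbook hand calculation", {
  st <- compute_gene_stats(c(2, 4), c(1, 3))
  expect_equal(st$t_stat, 1 / sqrt(2))
  expect_equal(st$log2_median_ratio, 1)
  # identity case
  same <- compute_gene_stats(c(1, 3), c(1, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$log2_median_ratio, 0)
  # antisymmetry under group swap
  a <- compute_gene_stats(c(2, 4, 5), c(1, 3, 3))
  b <- compute_gene_stats(c(1, 3, 3), c(2, 4, 5))
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$log2_median_ratio, -b$log2_median_ratio)
})

test_that("zero pooled variance yields 0 or a flagged signed infinity", {
  eq <- compute_gene_stats(c(2, 2), c(2, 2))
  expect_equal(eq$t_stat, 0)
  ne <- compute_gene_stats(c(3, 3), c(2, 2))
  expect_identical(ne$t_stat, Inf)
  expect_true(attr(ne, "zero_variance"))
})

test_that("2v2 designs enumerate exactly the 5 non-identity relabelings", {
  x <- matrix(rnorm(40), nrow = 10)
  null <- build_permutation_null(x[, 1:2], x[, 3:4])
  expect_identical(null$n_perms, 5L)
  expect_length(null$t_null, 50L)
  # a pure-noise pooled null M is centred near zero
  se <- stats::sd(null$m_null) / sqrt(length(null$m_null))
  expect_lt(abs(mean(null$m_null)), 3 * se + 1e-9)
  # fixed seed reproducibility when sampling engages
  big <- matrix(rnorm(10 * 12), nrow = 10)
  n1 <- build_permutation_null(big[, 1:6], big[, 7:12], max_perms = 20,
                               seed = 5)
  n2 <- build_permutation_null(big[, 1:6], big[, 7:12], max_perms = 20,
                               seed = 5)
  expect_identical(n1$m_null, n2$m_null)
})

test_that("empirical p-values respect the pseudocount floor and sides", {
  null <- seq_len(999) / 100
  expect_equal(empirical_pvalue(1000, null), 1 / 1000)
  expect_equal(empirical_pvalue(stats::median(null), null), 0.5,
               tolerance = 0.01)
  # normal tail oracle
  set.seed(77)
  z <- rnorm(10000)
  p <- empirical_pvalue(1.6449, z)
  expect_equal(p, 0.05, tolerance = 3 * sqrt(0.05 * 0.95 / 10000) / 0.05)
  # negative observations mirror to the lower tail
  expect_equal(empirical_pvalue(-1000, null), 1 / 1000)
  expect_error(empirical_pvalue(1, numeric(0)), "empty null")
})

test_that("larger |observation| never increases its empirical p", {
  set.seed(3)
  null <- rnorm(500)
  obs <- sort(c(0.01, 0.5, 1, 2, 3))
  p <- empirical_pvalue(obs, null)
  expect_true(all(diff(p) <= 0))
  p_neg <- empirical_pvalue(-obs, null)
  expect_true(all(diff(p_neg) <= 0))
})

test_that("Stouffer combination matches the normal-CDF closed form", {
  expect_equal(stouffer_combine(0.5, 0.5), 0.5, tolerance = 1e-9)
  z <- qnorm(1 - 0.05)
  expect_equal(stouffer_combine(0.05, 0.05),
               1 - pnorm(2 * z / sqrt(2)), tolerance = 1e-12)
  expect_equal(stouffer_combine(0.05, 0.05), 0.01, tolerance = 1e-3)
  expect_equal(stouffer_combine(0.5, 0.05), 0.1224, tolerance = 1e-4)
  # clamping absorbs extremes without NaN
  expect_true(is.finite(stouffer_combine(1e-300, 1)))
  # closed form over a grid, to numerical precision
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(stouffer_combine(p1, p2),
               1 - pnorm((qnorm(1 - p1) + qnorm(1 - p2)) / sqrt(2)),
               tolerance = 1e-9)
})

test_that("the dual gate requires both significance and fold change", {
  null <- structure(list(t_null = rnorm(5000), m_null = rnorm(5000, 0, 0.3),
                         n_perms = 5L, scheme = "test"),
                    class = "deg_null")
  cutoff <- unname(quantile(abs(null$m_null), 0.95))
  # gene 3: fold change barely passes but t carries no evidence, so the
  # combined p stays above alpha -> N (the p gate blocks it)
  stats <- list(t_stat = c(6, 6, 0, -6),
                log2_median_ratio = c(cutoff * 2, cutoff / 2,
                                      cutoff * 1.001, -cutoff * 2))
  out <- call_degs(stats, null, genes = paste0("g", 1:4))
  expect_identical(out$call, c("U", "N", "N", "D"))
  expect_equal(out$fc_cutoff[1], cutoff)
  # direction consistency among called genes
  expect_true(all(out$log2_median_ratio[out$call == "U"] > 0))
  expect_true(all(out$log2_median_ratio[out$call == "D"] < 0))
})

test_that("planted effects are called in the planted direction", {
  sim <- simulate_expression_study(sim_config(
    n_background_genes = 200, genes_per_structure = 30, structures = 10,
    effect_delta = 2, noise_sd = 0.25, fraction_repressed = 0, seed = 41))
  d <- deg_test(sim$study, "arr1/10/12", seed = 41)
  planted <- !is.na(sim$truth$cluster)
  # activated targets of a 1&10&12 structure drop in the triple mutant
  expect_gt(mean(d$call[planted] == "D"), 0.99)
})

test_that("fc cutoff is per comparison and data derived", {
  sim <- small_sim(seed = 19)
  degs <- deg_analysis(sim$study, seed = 19)
  cutoffs <- vapply(degs, function(t) t$fc_cutoff[1], numeric(1))
  expect_gt(length(unique(cutoffs)), 1L)
  expect_true(all(cutoffs > 0))
})
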