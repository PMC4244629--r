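# Synthetic-data generators: planted means, determinism, graph and
# annotation properties.

test_that("planted means follow the Boolean model (1|12 example)", {
  # activated gene under 1|12, delta = 2: drops only where both ARR1 and
  # ARR12 are deleted; check sample means at large n against closed form
  n_rep <- 200L
  cfg <- sim_config(n_background_genes = 0, genes_per_structure = 1,
                    structures = 7, effect_delta = 2, noise_sd = 0.25,
                    baseline_mu = 8, baseline_sd = 0,
                    fraction_repressed = 0, ck_fraction = 0,
                    n_replicates = n_rep, seed = 21)
  sim <- simulate_expression_study(cfg)
  s <- sim$study
  cond_mean <- function(g) mean(s$exprs[1, s$samples$genotype == g &
                                          s$samples$treatment == "none"])
  tol <- 3 * 0.25 / sqrt(n_rep)
  expect_equal(cond_mean("WT"), 8, tolerance = tol)
  expect_equal(cond_mean("arr1"), 8, tolerance = tol)
  expect_equal(cond_mean("arr10/12"), 8, tolerance = tol)
  expect_equal(cond_mean("arr1/12"), 6, tolerance = tol)
  expect_equal(cond_mean("arr1/10/12"), 6, tolerance = tol)
})

test_that("repressed genes mirror the sign and CK shifts only WT+CK", {
  cfg <- sim_config(n_background_genes = 0, genes_per_structure = 1,
                    structures = 10, effect_delta = 2, noise_sd = 0.25,
                    baseline_sd = 0, fraction_repressed = 1,
                    ck_fraction = 1, ck_effect_delta = 3,
                    n_replicates = 100L, seed = 22)
  sim <- simulate_expression_study(cfg)
  s <- sim$study
  mu <- cfg$baseline_mu
  m <- function(g, tr) mean(s$exprs[1, s$samples$genotype == g &
                                      s$samples$treatment == tr])
  expect_equal(m("arr1", "none"), mu + 2, tolerance = 0.1)
  expect_equal(m("WT", "mock"), mu, tolerance = 0.1)
  expect_equal(m("WT", "CK"), mu + sim$truth$ck_sign[1] * 3,
               tolerance = 0.1)
})

test_that("identical seed and config reproduce bit-identical output", {
  a <- simulate_expression_study(sim_config(n_background_genes = 40,
                                            genes_per_structure = 2,
                                            seed = 5))
  b <- simulate_expression_study(sim_config(n_background_genes = 40,
                                            genes_per_structure = 2,
                                            seed = 5))
  expect_identical(a$study$exprs, b$study$exprs)
  expect_identical(a$truth, b$truth)
  g1 <- simulate_ppi_network(50, 2, seed = 9)
  g2 <- simulate_ppi_network(50, 2, seed = 9)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  s1 <- simulate_annotation_sets(letters, 5, c(2, 5), seed = 3)
  s2 <- simulate_annotation_sets(letters, 5, c(2, 5), seed = 3)
  expect_identical(s1, s2)
})

test_that("null planted effect is indistinguishable from background", {
  cfg <- sim_config(n_background_genes = 500, genes_per_structure = 10,
                    effect_delta = 0, seed = 31)
  sim <- simulate_expression_study(cfg)
  d <- deg_test(sim$study, "arr1/10/12", seed = 31)
  rate <- mean(d$call != "N")
  se <- sqrt(0.05 * 0.95 / nrow(d))
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("PPI generator yields simple connected heavy-tailed graphs", {
  g <- simulate_ppi_network(1000, 2, seed = 13)
  deg <- igraph::degree(g)
  expect_identical(sum(deg), 2L * igraph::ecount(g))     # handshake
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))
  expect_gt(max(deg), 5 * stats::median(deg))
  # m = 1 on 5 nodes forces a tree
  tree <- simulate_ppi_network(5, 1, seed = 1)
  expect_identical(igraph::ecount(tree), 4)
  expect_error(simulate_ppi_network(2, 2), "n_nodes > attach_m")
})

test_that("annotation generator plants terms and respects the universe", {
  genes <- sprintf("g%03d", 1:100)
  sets <- simulate_annotation_sets(genes, n_terms = 10,
                                   size_range = c(5, 20),
                                   planted = list(MY_TERM = genes[1:8]),
                                   seed = 2)
  expect_identical(sets$MY_TERM, genes[1:8])
  expect_true(all(unlist(sets) %in% genes))
  expect_length(simulate_annotation_sets(genes, 0, c(5, 10), seed = 1), 0L)
  expect_error(simulate_annotation_sets(genes, 5, c(5, 500), seed = 1),
               "size_range")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(effect_delta = -1), "effect_delta")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(fraction_repressed = 1.2), "fraction_repressed")
})

test_that("multi-probe mode collapses back to one row per gene", {
  cfg <- sim_config(n_background_genes = 30, genes_per_structure = 0,
                    multi_probe = 3, seed = 8)
  sim <- simulate_expression_study(cfg)
  expect_identical(nrow(sim$study$exprs), 90L)
  collapsed <- collapse_probes(sim$study, sim$probe_map)
  expect_identical(nrow(collapsed$exprs), 30L)
  # probe order permutation leaves the collapsed values unchanged
  perm <- sample(nrow(sim$study$exprs))
  shuffled <- expression_study(sim$study$exprs[perm, ], sim$study$samples)
  collapsed2 <- collapse_probes(shuffled, sim$probe_map)
  expect_equal(collapsed$exprs[rownames(collapsed$exprs), ],
               collapsed2$exprs[rownames(collapsed$exprs), ])
})
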