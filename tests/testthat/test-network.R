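# Hub/clustering-coefficient significance and fraction tables.

test_that("star-graph hub calls match the exact ECDF hand calculation", {
  g <- igraph::make_star(101, mode = "undirected")
  igraph::V(g)$name <- paste0("n", 1:101)
  ns <- node_significance(g, "degree", mode = "exact")
  centre <- ns[ns$value == 100, ]
  expect_equal(centre$p, 1 / 101)
  expect_true(centre$significant)
  leaves <- ns[ns$value == 1, ]
  expect_true(all(leaves$p == 1))
  expect_false(any(leaves$significant))
})

test_that("regular graphs have no hubs", {
  g <- igraph::make_ring(20)
  igraph::V(g)$name <- paste0("n", 1:20)
  ns <- node_significance(g, "degree")
  expect_true(all(ns$p == 1))
  expect_false(any(ns$significant))
})

test_that("clustering coefficients match the closed-form cases", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(clustering_coefficients(tri)), rep(1, 3))
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:6)
  expect_equal(unname(clustering_coefficients(star)[1]), 0)
  # 4-cycle with one chord: the chord endpoints see 2 of 3 neighbour pairs
  g <- igraph::graph_from_edgelist(
    rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A"), c("A", "C")),
    directed = FALSE)
  cc <- clustering_coefficients(g)
  expect_equal(unname(cc["A"]), 2 / 3)
  expect_equal(unname(cc["B"]), 1)
})

test_that("coefficients match brute-force triangle counting on random graphs", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.7))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(unname(clustering_coefficients(g)), brute_force_cc(adj))
  }
})

test_that("sampled p-values track exact p-values within binomial error", {
  g <- simulate_ppi_network(1000, 2, seed = 17)
  exact <- node_significance(g, "degree", mode = "exact")
  sampled <- node_significance(g, "degree", mode = "sampled",
                               n_samples = 20000, seed = 17)
  se <- sqrt(exact$p * (1 - exact$p) / 20000)
  expect_true(all(abs(sampled$p - exact$p) <= 3 * se + 1e-4))
  # sampled mode reproducible under fixed seed
  sampled2 <- node_significance(g, "degree", mode = "sampled",
                                n_samples = 20000, seed = 17)
  expect_identical(sampled$p, sampled2$p)
})

test_that("hub calls are invariant to node relabeling", {
  g <- simulate_ppi_network(200, 2, seed = 23)
  ns1 <- node_significance(g, "degree")
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  ns2 <- node_significance(g2, "degree")
  hubs1 <- sort(ns1$node[ns1$significant])
  hubs2 <- sort(ns2$node[ns2$significant])
  expect_identical(hubs1, hubs2)
})

test_that("fraction tables reproduce the worked percentages", {
  classes <- data.frame(
    gene_id = c(sprintf("a%03d", 1:24), sprintf("b%03d", 1:70)),
    class = c(rep("G2", 24), rep("G4", 70)), stringsAsFactors = FALSE)
  aba <- c(classes$gene_id, sprintf("x%03d", 1:(418 - 94)))
  out <- group_fraction_table(classes, list(ABA = aba))
  expect_equal(out$percent[out$class == "G2"], 5.7)
  expect_equal(out$percent[out$class == "G4"], 16.7)
  # toy arithmetic and empty intersection
  toy <- group_fraction_table(
    data.frame(gene_id = c("g1", "g2"), class = "G4"),
    list(S = c("g1", "g2", paste0("z", 1:8)), E = paste0("z", 9:10)))
  expect_equal(toy$percent[toy$set == "S" & toy$class == "G4"], 20.0)
  expect_equal(toy$percent[toy$set == "E"], 0.0)
  # fractions over disjoint classes sum to at most 1 within a set
  expect_lte(sum(out$fraction), 1)
})

test_that("layered sets are stratified and edge lists round-trip", {
  sets <- data.frame(hormone = "CK", gene_id = c("g1", "g2", "g3"),
                     layer = c("upstream", "upstream", "downstream"),
                     stringsAsFactors = FALSE)
  classes <- data.frame(gene_id = c("g1", "g3"), class = "G2",
                        stringsAsFactors = FALSE)
  out <- group_fraction_table(classes, sets)
  expect_setequal(out$layer, c("upstream", "downstream"))
  expect_equal(out$count[out$layer == "upstream"], 1L)
  g <- simulate_ppi_network(30, 1, seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, p)
  back <- read_edge_list(p)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
})
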