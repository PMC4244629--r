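# Shared fixtures built in code.

# small planted study reused by several test files
small_sim <- function(seed = 11, ...) {
  simulate_expression_study(sim_config(
    n_background_genes = 300, genes_per_structure = 8, seed = seed, ...))
}

# brute-force structure enumeration independent of the package's
# antichain code: iterate all 256 truth tables over presence masks,
# keep monotone non-constant, return sorted changed-set signatures
brute_force_changed_sets <- function() {
  sigs <- character(0)
  for (code in 0:255) {
    f <- as.integer(intToBits(code))[1:8]
    if (all(f == 0) || all(f == 1)) next
    mono <- TRUE
    for (a in 0:7) for (b in 0:7) {
      if (bitwAnd(a, b) == a && f[a + 1] > f[b + 1]) mono <- FALSE
    }
    if (!mono) next
    changed <- Filter(function(S) f[8 - S] == 0, 1:7)  # f[(7 - S) + 1]
    sigs <- c(sigs, paste(changed, collapse = ","))
  }
  sigs
}

# brute-force local clustering coefficient from an adjacency matrix
brute_force_cc <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}
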