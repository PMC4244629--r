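# Synthetic study generator with planted regulatory structures.
#
# Emulates the combinatorial deletion design: 8 genotypes untreated plus
# wild type under mock and cytokinin (CK) treatment, n biological
# replicates per condition, log2-scale intensities with i.i.d. Gaussian
# replicate noise.  Planted genes follow a monotone Boolean structure:
# an "activated" target sits at its baseline while the structure is
# satisfied and drops by effect_delta in any genotype whose deletion set
# switches the structure off; "repressed" targets mirror the sign.

#' Simulation configuration
#'
#' @param n_background_genes Unregulated genes drawn from the baseline
#'   distribution only.
#' @param genes_per_structure Planted genes per structure listed in
#'   `structures`.
#' @param structures Integer cluster indices (1-18) of structures to
#'   plant; defaults to the 15 conventional clusters.
#' @param effect_delta Log2 expression shift applied when a planted
#'   gene's structure is unsatisfied (>= 0).
#' @param noise_sd Replicate Gaussian noise SD, log2 units (> 0).
#' @param baseline_mu,baseline_sd Mean and SD of per-gene baseline log2
#'   intensity.
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param fraction_repressed Fraction of planted genes whose targets rise
#'   when the logic fails (mutant call U) rather than fall (call D).
#' @param ck_fraction Fraction of all genes designated CK-responsive.
#' @param ck_effect_delta Log2 shift added to CK-responsive genes in the
#'   wild-type + CK condition (sign drawn per gene: half induced, half
#'   repressed).
#' @param multi_probe Probes per gene (1 = one probe per gene; > 1
#'   exercises probe-to-gene collapsing via per-probe offsets).
#' @param probe_offset_sd SD of the per-probe baseline offset when
#'   `multi_probe > 1`.
#' @param seed RNG seed consumed by [simulate_expression_study()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_background_genes = 5000L,
                       genes_per_structure = 40L,
                       structures = 1:15,
                       effect_delta = 2,
                       noise_sd = 0.25,
                       baseline_mu = 8,
                       baseline_sd = 1.5,
                       n_replicates = 2L,
                       fraction_repressed = 0.5,
                       ck_fraction = 0.1,
                       ck_effect_delta = 2,
                       multi_probe = 1L,
                       probe_offset_sd = 0.3,
                       seed = 1L) {
  cfg <- list(n_background_genes = as.integer(n_background_genes),
              genes_per_structure = as.integer(genes_per_structure),
              structures = as.integer(structures),
              effect_delta = effect_delta, noise_sd = noise_sd,
              baseline_mu = baseline_mu, baseline_sd = baseline_sd,
              n_replicates = as.integer(n_replicates),
              fraction_repressed = fraction_repressed,
              ck_fraction = ck_fraction,
              ck_effect_delta = ck_effect_delta,
              multi_probe = as.integer(multi_probe),
              probe_offset_sd = probe_offset_sd,
              seed = as.integer(seed))
  if (cfg$n_background_genes < 0L || cfg$genes_per_structure < 0L)
    stop("gene counts must be non-negative")
  if (cfg$effect_delta < 0) stop("effect_delta must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (cfg$fraction_repressed < 0 || cfg$fraction_repressed > 1)
    stop("fraction_repressed must be in [0, 1]")
  if (cfg$ck_fraction < 0 || cfg$ck_fraction > 1)
    stop("ck_fraction must be in [0, 1]")
  if (!all(cfg$structures %in% 1:18))
    stop("structures must be cluster indices in 1..18")
  if (cfg$multi_probe < 1L) stop("multi_probe must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# draw a planted-truth table from a config (RNG already seeded)
draw_truth <- function(config) {
  n_planted <- length(config$structures) * config$genes_per_structure
  n <- config$n_background_genes + n_planted
  gene_id <- sprintf("g%05d", seq_len(n))
  cluster <- c(rep(config$structures, each = config$genes_per_structure),
               rep(NA_integer_, config$n_background_genes))
  direction <- rep(NA_character_, n)
  if (n_planted > 0L) {
    direction[seq_len(n_planted)] <-
      ifelse(stats::runif(n_planted) < config$fraction_repressed,
             "repressed", "activated")
  }
  ck <- stats::runif(n) < config$ck_fraction
  ck_sign <- ifelse(stats::runif(n) < 0.5, 1, -1)
  ck_sign[!ck] <- 0
  data.frame(gene_id = gene_id, cluster = cluster, direction = direction,
             baseline = stats::rnorm(n, config$baseline_mu,
                                     config$baseline_sd),
             ck_responsive = ck, ck_sign = ck_sign,
             stringsAsFactors = FALSE)
}

#' Simulate an expression study with planted regulatory structures
#'
#' Generates the full design (8 genotypes untreated, wild type mock- and
#' CK-treated, `n_replicates` each) as a log2-intensity matrix.  For an
#' activated planted gene with structure f, the expected value in a
#' genotype with deletion set S is `baseline - effect_delta` when f is
#' unsatisfied under S and `baseline` otherwise; repressed genes flip the
#' sign.  CK-responsive genes shift by `ck_effect_delta` (gene-specific
#' sign) in the wild-type + CK condition only.  Replicate noise is
#' i.i.d. Gaussian on the log2 scale.
#'
#' @param config A [sim_config()].
#' @param truth Optional planted-truth data frame (columns `gene_id`,
#'   `cluster` (1-18 or NA for background), `direction`
#'   ("activated"/"repressed"), `baseline`, `ck_responsive`, `ck_sign`);
#'   drawn from `config` when omitted.
#' @return A list with elements `study` (an [expression_study()]) and
#'   `truth` (the planted-truth data frame, with the structure label
#'   joined in).  With `multi_probe > 1` the study rows are probes and a
#'   `probe_map` element links probes to genes.
#' @export
#' @examples
#' sim <- simulate_expression_study(sim_config(
#'   n_background_genes = 50, genes_per_structure = 2, seed = 7))
#' dim(sim$study$exprs)
simulate_expression_study <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(truth)) truth <- draw_truth(config)
  stopifnot(is.data.frame(truth),
            all(c("gene_id", "cluster", "direction", "baseline",
                  "ck_responsive") %in% names(truth)))
  if (is.null(truth$ck_sign))
    truth$ck_sign <- ifelse(truth$ck_responsive, 1, 0)
  cat3 <- enumerate_structures(3L)
  changed_by_idx <- lapply(cat3, `[[`, "changed")
  labels <- vapply(cat3, `[[`, character(1), "label")

  samples <- data.frame(
    genotype = c(rep(arr_genotypes(), each = 1L), "WT", "WT"),
    treatment = c(rep("none", 8L), "mock", "CK"),
    stringsAsFactors = FALSE)
  samples <- samples[rep(seq_len(nrow(samples)),
                         each = config$n_replicates), , drop = FALSE]
  samples$replicate <- rep(seq_len(config$n_replicates), times = 10L)
  samples$sample_id <- paste(gsub("/", ".", samples$genotype, fixed = TRUE),
                             samples$treatment,
                             paste0("r", samples$replicate), sep = "_")
  rownames(samples) <- NULL
  samples <- samples[, c("sample_id", "genotype", "treatment", "replicate")]

  gmask <- genotype_masks()[samples$genotype]
  n_genes <- nrow(truth)
  expected <- matrix(rep(truth$baseline, times = nrow(samples)),
                     nrow = n_genes)
  planted <- which(!is.na(truth$cluster))
  if (length(planted) > 0L) {
    dir_sign <- ifelse(truth$direction[planted] == "repressed", 1, -1)
    for (j in seq_len(nrow(samples))) {
      if (gmask[j] == 0L) next
      unsat <- vapply(truth$cluster[planted], function(cl)
        gmask[j] %in% changed_by_idx[[cl]], logical(1))
      expected[planted, j] <- expected[planted, j] +
        dir_sign * config$effect_delta * unsat
    }
  }
  ck_col <- samples$treatment == "CK" & samples$genotype == "WT"
  if (any(ck_col)) {
    expected[, ck_col] <- expected[, ck_col] +
      truth$ck_sign * config$ck_effect_delta
  }

  probe_map <- NULL
  if (config$multi_probe > 1L) {
    k <- config$multi_probe
    ridx <- rep(seq_len(n_genes), each = k)
    expected <- expected[ridx, , drop = FALSE] +
      stats::rnorm(n_genes * k, 0, config$probe_offset_sd)
    probe_id <- paste0(truth$gene_id[ridx], ".p", rep(seq_len(k), n_genes))
    probe_map <- data.frame(probe_id = probe_id,
                            gene_id = truth$gene_id[ridx],
                            stringsAsFactors = FALSE)
    rown <- probe_id
  } else {
    rown <- truth$gene_id
  }
  mat <- expected + stats::rnorm(length(expected), 0, config$noise_sd)
  dimnames(mat) <- list(rown, samples$sample_id)

  truth$label <- ifelse(is.na(truth$cluster), NA_character_,
                        labels[truth$cluster])
  out <- list(study = expression_study(mat, samples), truth = truth)
  if (!is.null(probe_map)) out$probe_map <- probe_map
  out
}

#' Simulate a protein-protein interaction network
#'
#' Preferential-attachment (Barabasi-Albert) graph: simple, connected,
#' heavy-tailed degree distribution, standing in for a curated
#' interactome when exercising the hub/clustering-coefficient stage.
#'
#' @param n_nodes Number of nodes (> `attach_m`).
#' @param attach_m Edges attached per incoming node (>= 1).
#' @param node_names Optional node names (e.g. gene IDs); defaults to
#'   `n1..nN`.
#' @param seed RNG seed.
#' @return An undirected [igraph::igraph] graph with named vertices.
#' @export
simulate_ppi_network <- function(n_nodes, attach_m = 2L, node_names = NULL,
                                 seed = 1L) {
  n_nodes <- as.integer(n_nodes); attach_m <- as.integer(attach_m)
  if (attach_m < 1L || n_nodes <= attach_m)
    stop("need n_nodes > attach_m >= 1")
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
  if (is.null(node_names)) node_names <- paste0("n", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes)
  igraph::V(g)$name <- node_names
  g
}

#' Simulate annotation gene sets
#'
#' Random term-to-gene-set map over a gene universe, with optional
#' planted terms containing exactly a specified subset (for enrichment
#' power checks).
#'
#' @param genes Gene universe.
#' @param n_terms Number of random terms.
#' @param size_range Length-2 integer range of random term sizes.
#' @param planted Named list of gene vectors; each becomes a term with
#'   exactly those genes.
#' @param seed RNG seed.
#' @return Named list of gene-ID vectors (GMT-writable).
#' @export
simulate_annotation_sets <- function(genes, n_terms = 50L,
                                     size_range = c(10L, 50L),
                                     planted = list(), seed = 1L) {
  stopifnot(length(size_range) == 2L, size_range[1] >= 1L)
  if (max(size_range) > length(genes))
    stop("size_range exceeds the gene universe")
  if (length(planted) > 0L &&
      !all(unlist(planted) %in% genes))
    stop("planted subsets must be drawn from the gene universe")
  set.seed(seed)
  sets <- list()
  if (n_terms > 0L) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("TERM%04d", seq_len(n_terms))
  }
  c(sets, planted)
}

#' Simulate hormone signaling gene lists with layer labels
#'
#' Stand-in for curated hormone signaling networks: per hormone, a random
#' gene list with each gene assigned to the upstream, intermediate or
#' downstream signaling layer.
#'
#' @param genes Gene universe.
#' @param hormones Hormone labels.
#' @param genes_per_hormone Genes drawn per hormone.
#' @param layer_probs Sampling probabilities for the three layers.
#' @param seed RNG seed.
#' @return Data frame with columns `hormone`, `gene_id`, `layer`.
#' @export
simulate_hormone_layers <- function(genes,
                                    hormones = c("CK", "ABA", "ET", "JA",
                                                 "Aux", "GA", "BL"),
                                    genes_per_hormone = 60L,
                                    layer_probs = c(0.15, 0.35, 0.5),
                                    seed = 1L) {
  stopifnot(genes_per_hormone <= length(genes))
  set.seed(seed)
  do.call(rbind, lapply(hormones, function(h) {
    data.frame(hormone = h,
               gene_id = sample(genes, genes_per_hormone),
               layer = sample(c("upstream", "intermediate", "downstream"),
                              genes_per_hormone, replace = TRUE,
                              prob = layer_probs),
               stringsAsFactors = FALSE)
  }))
}
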