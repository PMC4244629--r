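# Empirical-null significance of node degree and clustering coefficient,
# plus class-membership fraction tables over gene sets and signaling
# layers.

#' Local clustering coefficients
#'
#' `c = 2 * (edges among neighbours) / (k * (k - 1))` for degree
#' `k >= 2`; nodes with fewer than two neighbours get 0.
#'
#' @param network Undirected simple [igraph::igraph] graph.
#' @return Named numeric vector of per-node coefficients.
#' @export
clustering_coefficients <- function(network) {
  stopifnot(igraph::is_igraph(network))
  cc <- igraph::transitivity(network, type = "localundirected",
                             isolates = "zero")
  cc[is.na(cc)] <- 0           # degree-1 nodes
  names(cc) <- igraph::V(network)$name
  cc
}

#' Empirical-null significance of a node statistic
#'
#' Upper-tail significance of each node's degree or clustering
#' coefficient against the network-wide empirical distribution of the
#' same statistic.  `mode = "exact"` (default) uses the exact upper-tail
#' ECDF over all nodes, `p = #\{values >= observed\} / n_nodes`;
#' `mode = "sampled"` draws `n_samples` values with replacement (seeded)
#' and applies the add-one pseudocount,
#' `p = (1 + #\{sampled >= observed\}) / (1 + n_samples)`.  Nodes with
#' `p < alpha` are flagged (hub-like for degree, densely clustered for
#' the clustering coefficient).
#'
#' @param network Undirected simple [igraph::igraph] graph.
#' @param statistic `"degree"` or `"clustering_coefficient"`.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples Draws in sampled mode.
#' @param seed Seed for sampled mode.
#' @param alpha Flagging threshold.
#' @return Data frame: `node`, `value`, `p`, `significant`.
#' @export
#' @examples
#' g <- igraph::make_star(11, mode = "undirected")
#' igraph::V(g)$name <- paste0("n", 1:11)
#' node_significance(g, "degree")[1, ]
node_significance <- function(network,
                              statistic = c("degree",
                                            "clustering_coefficient"),
                              mode = c("exact", "sampled"),
                              n_samples = 100000L, seed = NULL,
                              alpha = 0.05) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(network))
  if (igraph::vcount(network) == 0L) stop("empty network")
  values <- switch(statistic,
                   degree = {
                     d <- igraph::degree(network)
                     names(d) <- igraph::V(network)$name
                     d
                   },
                   clustering_coefficient =
                     clustering_coefficients(network))
  if (mode == "exact") {
    sv <- sort(values)
    n <- length(sv)
    p <- (n - findInterval(values, sv, left.open = TRUE)) / n
  } else {
    if (!is.null(seed)) set.seed(seed)
    draws <- sort(sample(values, n_samples, replace = TRUE))
    n_ge <- n_samples - findInterval(values, draws, left.open = TRUE)
    p <- (1 + n_ge) / (1 + n_samples)
  }
  data.frame(node = if (is.null(names(values)))
    as.character(seq_along(values)) else names(values),
    value = unname(values), p = unname(p),
    significant = unname(p < alpha),
    stringsAsFactors = FALSE)
}

#' Fraction of a gene set falling in each regulatory class
#'
#' For each target set (e.g. a hormone signaling network, optionally
#' stratified by layer) and each class (group or cluster), the count of
#' member genes in that class and the fraction `count / |set|`, with the
#' percent reported to one decimal.
#'
#' @param classes Data frame with columns `gene_id` and `class` (one row
#'   per gene; e.g. "G2" or "C7").
#' @param sets Either a named list of gene-ID vectors, or a data frame
#'   with columns `set` (or `hormone`), `gene_id` and optionally `layer`.
#' @return Data frame: `set`, (`layer`,) `class`, `count`, `set_size`,
#'   `fraction`, `percent`.  Empty sets produce rows with `NA` fractions
#'   flagged via `empty_set`.
#' @export
#' @examples
#' classes <- data.frame(gene_id = c("a", "b"), class = c("G2", "G4"))
#' group_fraction_table(classes, list(ABA = c("a", "b", "c")))
group_fraction_table <- function(classes, sets) {
  stopifnot(all(c("gene_id", "class") %in% names(classes)))
  if (is.data.frame(sets)) {
    if ("hormone" %in% names(sets) && !"set" %in% names(sets))
      names(sets)[names(sets) == "hormone"] <- "set"
    stopifnot(all(c("set", "gene_id") %in% names(sets)))
    keys <- if ("layer" %in% names(sets))
      split(sets$gene_id, list(set = sets$set, layer = sets$layer),
            drop = TRUE, sep = "\r")
    else split(sets$gene_id, sets$set)
  } else {
    stopifnot(is.list(sets), !is.null(names(sets)))
    keys <- sets
  }
  class_levels <- sort(unique(classes$class))
  rows <- lapply(names(keys), function(k) {
    members <- unique(keys[[k]])
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    size <- length(members)
    in_class <- classes[classes$gene_id %in% members, , drop = FALSE]
    counts <- table(factor(in_class$class, levels = class_levels))
    df <- data.frame(set = parts[1], class = class_levels,
                     count = as.integer(counts), set_size = size,
                     stringsAsFactors = FALSE)
    if (length(parts) > 1L) df$layer <- parts[2]
    df
  })
  out <- do.call(rbind, rows)
  out$fraction <- ifelse(out$set_size > 0, out$count / out$set_size,
                         NA_real_)
  out$percent <- round(100 * out$fraction, 1)
  out$empty_set <- out$set_size == 0
  if ("layer" %in% names(out))
    out <- out[, c("set", "layer", "class", "count", "set_size",
                   "fraction", "percent", "empty_set")]
  out
}

#' Read an undirected edge list
#'
#' Two-column TSV (or SIF with an interaction-type middle column);
#' self-loops and duplicate edges are dropped.
#'
#' @param path Input path.
#' @param format `"tsv"` (two columns) or `"sif"` (three columns,
#'   interaction type in the middle).
#' @return Undirected simple [igraph::igraph] graph.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, header = (format == "tsv"),
                           stringsAsFactors = FALSE)
  edges <- if (format == "sif") tab[, c(1L, 3L)] else tab[, 1:2]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Write an undirected edge list to TSV
#'
#' @param network [igraph::igraph] graph.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.table(data.frame(node_a = el[, 1], node_b = el[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
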