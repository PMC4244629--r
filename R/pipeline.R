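# End-to-end orchestration: normalize -> DEG statistics -> logic
# inference -> network / enrichment / CK-response stages, with a
# machine-readable run report.

#' Up/down/total count table
#'
#' The aggregation used throughout reporting: per category, the up- and
#' down-regulated counts and their total.
#'
#' @param up,down Integer vectors (same length, optionally named).
#' @param labels Category labels (defaults to the names of `up`).
#' @return Data frame: `label`, `up`, `down`, `total`.
#' @export
report_count_table <- function(up, down, labels = names(up)) {
  stopifnot(length(up) == length(down))
  if (is.null(labels)) labels <- as.character(seq_along(up))
  data.frame(label = labels, up = as.integer(up), down = as.integer(down),
             total = as.integer(up) + as.integer(down),
             stringsAsFactors = FALSE)
}

# per-comparison U/D counts and pooled counts by mutant class; a gene
# counts once per direction within a class (union over the class's
# comparisons)
deg_count_summary <- function(degs) {
  cmp <- intersect(arr_comparisons(), names(degs))
  per_cmp <- report_count_table(
    vapply(degs[cmp], function(t) sum(t$call == "U"), integer(1)),
    vapply(degs[cmp], function(t) sum(t$call == "D"), integer(1)),
    labels = cmp)
  classes <- list(single = cmp[1:3], double = cmp[4:6], triple = cmp[7])
  pooled <- report_count_table(
    vapply(classes, function(g) length(unique(unlist(lapply(degs[g],
      function(t) t$gene_id[t$call == "U"])))), integer(1)),
    vapply(classes, function(g) length(unique(unlist(lapply(degs[g],
      function(t) t$gene_id[t$call == "D"])))), integer(1)),
    labels = names(classes))
  if ("CK" %in% names(degs)) {
    ck <- degs[["CK"]]
    pooled <- rbind(pooled, report_count_table(
      sum(ck$call == "U"), sum(ck$call == "D"), labels = "CK"))
  }
  list(per_comparison = per_cmp, by_class = pooled)
}

#' Run the full analysis pipeline
#'
#' Quantile-normalizes the study, runs the integrative DEG statistic over
#' the seven mutant comparisons (plus the CK comparison when present),
#' encodes patterns, maps them to regulatory structures, selects major
#' clusters and assigns groups, and - when the corresponding inputs are
#' supplied - computes hub/clustering-coefficient significance over an
#' interaction network, hormone-layer fraction tables, per-group gene-set
#' enrichment and the CK-response classification.
#'
#' @param study An [expression_study()] (or the list returned by
#'   [simulate_expression_study()], whose truth table is then used for
#'   recovery reporting).
#' @param network Optional [igraph::igraph] interaction network.
#' @param annotations Optional named list of annotation gene sets.
#' @param hormone_sets Optional hormone/layer data frame
#'   (see [simulate_hormone_layers()]).
#' @param normalize Quantile-normalize before testing.
#' @param alpha,fc_quantile,max_perms DEG parameters, see [deg_test()].
#' @param mode,percentile,catalog Logic parameters, see
#'   [assign_clusters()] and [cluster_select_group()].
#' @param network_mode,n_samples Network-significance parameters, see
#'   [node_significance()].
#' @param enrich_variant,enrich_threshold Enrichment parameters, see
#'   [fisher_enrichment()].
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @param outdir Optional output directory; when given, every stage's
#'   table is written as TSV and the report as JSON.
#' @return Object of class `arrlogic_result`: list with `degs`,
#'   `patterns`, `clusters`, `node_stats`, `fractions`, `enrichment`,
#'   `ck`, `truth`, `recovery`, `report` and `params`.
#' @export
run_pipeline <- function(study, network = NULL, annotations = NULL,
                         hormone_sets = NULL, normalize = TRUE,
                         alpha = 0.05, fc_quantile = 0.95,
                         max_perms = 1000L,
                         mode = c("closure", "strict"),
                         percentile = 50,
                         catalog = c("core15", "all18"),
                         network_mode = c("exact", "sampled"),
                         n_samples = 100000L,
                         enrich_variant = c("fisher", "ease"),
                         enrich_threshold = 0.1,
                         seed = 1L, outdir = NULL) {
  mode <- match.arg(mode)
  catalog <- match.arg(catalog)
  network_mode <- match.arg(network_mode)
  enrich_variant <- match.arg(enrich_variant)
  truth <- NULL
  if (!inherits(study, "expression_study") && is.list(study) &&
      !is.null(study$study)) {
    truth <- study$truth
    study <- study$study
  }
  stopifnot(inherits(study, "expression_study"))
  if (normalize) study <- quantile_normalize(study)

  degs <- deg_analysis(study, alpha = alpha, fc_quantile = fc_quantile,
                       max_perms = max_perms, seed = seed)
  patterns <- encode_patterns(degs)
  clusters <- assign_clusters(patterns, mode = mode, catalog = catalog)
  clusters <- cluster_select_group(clusters, percentile = percentile,
                                   n_catalog =
                                     if (catalog == "core15") 15L else 18L)

  node_stats <- NULL
  hub_counts <- NULL
  if (!is.null(network)) {
    node_stats <- list(
      degree = node_significance(network, "degree", mode = network_mode,
                                 n_samples = n_samples,
                                 seed = child_seed(seed, 20L)),
      clustering_coefficient = node_significance(
        network, "clustering_coefficient", mode = network_mode,
        n_samples = n_samples, seed = child_seed(seed, 21L)))
    deg_dir <- clusters[clusters$status == "mapped",
                        c("gene_id", "direction")]
    hub_counts <- lapply(node_stats, function(ns) {
      sig <- ns$node[ns$significant]
      hit <- deg_dir[deg_dir$gene_id %in% sig, , drop = FALSE]
      report_count_table(sum(hit$direction == "U"),
                         sum(hit$direction == "D"), labels = "significant")
    })
  }

  fractions <- NULL
  if (!is.null(hormone_sets)) {
    grp <- clusters[clusters$selected & !is.na(clusters$group),
                    c("gene_id", "group")]
    grp$class <- paste0("G", grp$group)
    fractions <- group_fraction_table(grp[, c("gene_id", "class")],
                                      hormone_sets)
  }

  enrich <- NULL
  if (!is.null(annotations)) {
    universe <- clusters$gene_id
    grp <- clusters[clusters$selected & !is.na(clusters$group), ,
                    drop = FALSE]
    enrich <- lapply(split(grp$gene_id, paste0("G", grp$group)),
                     function(q) fisher_enrichment(
                       q, annotations, universe,
                       variant = enrich_variant,
                       threshold = enrich_threshold))
  }

  ck <- NULL
  if ("CK" %in% names(degs))
    ck <- classify_ck_overlap(degs[["CK"]], clusters, patterns)

  recovery <- if (!is.null(truth)) structure_recovery(clusters, truth)
  counts <- deg_count_summary(degs)
  report <- list(
    n_genes = nrow(study$exprs),
    n_samples = ncol(study$exprs),
    comparisons = setdiff(names(degs), "CK"),
    deg_counts = counts$per_comparison,
    deg_class_counts = counts$by_class,
    cluster_sizes = attr(clusters, "sizes"),
    selection_thresholds = attr(clusters, "thresholds"),
    selected_clusters = sort(unique(
      clusters$cluster[clusters$selected])),
    structures_mapped = sort(unique(
      clusters$cluster[clusters$status == "mapped"])),
    hub_counts = hub_counts,
    ck_summary = if (!is.null(ck)) ck$summary,
    recovery = recovery,
    params = list(alpha = alpha, fc_quantile = fc_quantile,
                  max_perms = max_perms, mode = mode,
                  percentile = percentile, catalog = catalog,
                  network_mode = network_mode,
                  enrich_variant = enrich_variant,
                  enrich_threshold = enrich_threshold, seed = seed),
    version = as.character(utils::packageVersion("arrlogic")))

  out <- structure(list(degs = degs, patterns = patterns,
                        clusters = clusters, node_stats = node_stats,
                        fractions = fractions, enrichment = enrich,
                        ck = ck, truth = truth, recovery = recovery,
                        report = report),
                   class = "arrlogic_result")
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

# write every stage's table plus the JSON report
write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_deg_tables(result$degs, file.path(outdir, "deg"))
  wt <- function(x, nm) utils::write.table(
    x, file.path(outdir, nm), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(result$patterns, "patterns.tsv")
  wt(result$clusters, "clusters.tsv")
  if (!is.null(result$node_stats)) {
    wt(result$node_stats$degree, "node_degree.tsv")
    wt(result$node_stats$clustering_coefficient, "node_cc.tsv")
  }
  if (!is.null(result$fractions)) wt(result$fractions, "fractions.tsv")
  if (!is.null(result$ck)) {
    wt(result$ck$table, "ck_overlap.tsv")
    wt(result$ck$summary, "ck_summary.tsv")
  }
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment))
      wt(result$enrichment[[nm]], paste0("enrichment_", nm, ".tsv"))
  }
  cat3 <- structure_catalog("all18")
  wt(cat3, "structure_catalog.tsv")
  rep <- result$report
  rep$cluster_sizes <- as.data.frame.matrix(rep$cluster_sizes)
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.arrlogic_result <- function(x, ...) {
  cat("arrlogic pipeline result\n")
  cat("  genes:", x$report$n_genes, " samples:", x$report$n_samples, "\n")
  cat("  DEG counts by comparison:\n")
  print(x$report$deg_counts, row.names = FALSE)
  cat("  structures mapped:",
      paste(x$report$structures_mapped, collapse = ","), "\n")
  cat("  selected clusters:",
      paste(x$report$selected_clusters, collapse = ","), "\n")
  if (!is.null(x$recovery))
    cat(sprintf("  planted-structure recovery: %.1f%% of %d genes\n",
                100 * x$recovery$recovery, x$recovery$n_planted))
  invisible(x)
}

#' @export
summary.arrlogic_result <- function(object, ...) {
  print(object)
  cat("  cluster sizes (direction x cluster):\n")
  print(object$report$cluster_sizes)
  if (!is.null(object$ck)) {
    cat("  CK overlap summary:\n")
    print(object$ck$summary, row.names = FALSE)
  }
  invisible(object$report)
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the arguments of [run_pipeline()] and
#' [sim_config()] (under a `simulate:` block).  Requires the `yaml`
#' package.
#'
#' @param path Path to a YAML config.
#' @return Named list of parameters.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  yaml::read_yaml(path)
}
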