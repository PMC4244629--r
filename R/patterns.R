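# Pattern encoding and structure mapping.
#
# Each gene's calls over the seven mutant comparisons form a U/D/N
# pattern.  A pattern with direction-consistent changes is mapped to the
# monotone structure whose predicted changed-comparison set matches the
# observed one, either exactly ("strict") or after superset closure
# ("closure", the default): if deleting S changes the gene, deleting any
# superset of S is implied to change it, which absorbs missed calls in
# implied comparisons.

#' Encode per-gene U/D/N patterns over the seven comparisons
#'
#' @param degs A `deg_analysis` list (or named list of DEG tables)
#'   containing all seven mutant comparisons over one gene universe.
#' @return Data frame: `gene_id`, one U/D/N column per comparison
#'   (canonical order) and the collapsed 7-character `pattern` string.
#' @export
encode_patterns <- function(degs) {
  cmp <- arr_comparisons()
  if (!all(cmp %in% names(degs)))
    stop("missing comparison(s): ",
         paste(setdiff(cmp, names(degs)), collapse = ", "))
  genes <- degs[[cmp[1]]]$gene_id
  calls <- sapply(cmp, function(g) {
    tab <- degs[[g]]
    if (!identical(tab$gene_id, genes))
      stop("comparisons disagree on the gene universe (", g, ")")
    tab$call
  })
  out <- data.frame(gene_id = genes, calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$pattern <- do.call(paste0, as.data.frame(calls))
  out
}

# map one 7-character pattern string -> list(cluster, label, direction)
# or NULL when unmapped; catalogue entries carry changed-set signatures
map_one_pattern <- function(pattern, mode, sig_index, labels) {
  calls <- strsplit(pattern, "")[[1]]
  stopifnot(length(calls) == 7L)
  changed <- which(calls != "N")
  if (length(changed) == 0L) return(NULL)
  dirs <- unique(calls[changed])
  if (length(dirs) > 1L) return(NULL)            # inconsistent U/D mix
  O <- comparison_masks()[changed]
  if (mode == "closure") O <- closure_masks(O)
  sig <- paste(sort(O), collapse = ",")
  hit <- sig_index[[sig]]
  if (is.null(hit)) return(NULL)
  list(cluster = hit, label = labels[hit], direction = dirs)
}

#' Map U/D/N patterns to regulatory structures
#'
#' @param pattern A 7-character pattern string (or vector of them), or a
#'   character vector of 7 calls for a single gene.
#' @param mode `"closure"` (default) applies superset closure to the
#'   observed changed set before matching; `"strict"` requires an exact
#'   match.
#' @return Data frame with one row per pattern: `cluster` (1-18 or NA),
#'   `label`, `direction` ("U"/"D" or NA).  All-N and
#'   direction-inconsistent patterns are unmapped (NA), not errors.
#' @export
#' @examples
#' map_pattern_to_structure("NNNNDND")     # 1|12, direction D
map_pattern_to_structure <- function(pattern,
                                     mode = c("closure", "strict")) {
  mode <- match.arg(mode)
  if (length(pattern) == 7L && all(pattern %in% c("U", "D", "N")))
    pattern <- paste(pattern, collapse = "")
  cat3 <- enumerate_structures(3L)
  labels <- vapply(cat3, `[[`, character(1), "label")
  sig_index <- as.list(seq_along(cat3))
  names(sig_index) <- vapply(cat3, function(s)
    paste(s$changed, collapse = ","), character(1))
  rows <- lapply(pattern, function(p) {
    hit <- map_one_pattern(p, mode, sig_index, labels)
    if (is.null(hit))
      data.frame(cluster = NA_integer_, label = NA_character_,
                 direction = NA_character_, stringsAsFactors = FALSE)
    else
      data.frame(cluster = hit$cluster, label = hit$label,
                 direction = hit$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign genes to regulatory clusters
#'
#' Maps every gene's pattern (memoized over the distinct patterns) and
#' labels each gene `all_n` (no change anywhere), `unmapped`
#' (inconsistent directions or no matching structure) or `mapped`.
#'
#' @param patterns Result of [encode_patterns()].
#' @param mode Mapping mode, see [map_pattern_to_structure()].
#' @param catalog `"core15"` (default) reports only the 15 conventional
#'   clusters - genes matching the three `x&(y|z)` structures are treated
#'   as unmapped; `"all18"` reports all 18.
#' @return Data frame: `gene_id`, `pattern`, `cluster`, `label`,
#'   `direction`, `status`.
#' @export
assign_clusters <- function(patterns, mode = c("closure", "strict"),
                            catalog = c("core15", "all18")) {
  mode <- match.arg(mode)
  catalog <- match.arg(catalog)
  upat <- unique(patterns$pattern)
  mapped <- map_pattern_to_structure(upat, mode = mode)
  if (catalog == "core15") {
    drop <- !is.na(mapped$cluster) & mapped$cluster > 15L
    mapped$cluster[drop] <- NA_integer_
    mapped$label[drop] <- NA_character_
    mapped$direction[drop] <- NA_character_
  }
  ix <- match(patterns$pattern, upat)
  out <- data.frame(gene_id = patterns$gene_id,
                    pattern = patterns$pattern,
                    cluster = mapped$cluster[ix],
                    label = mapped$label[ix],
                    direction = mapped$direction[ix],
                    stringsAsFactors = FALSE)
  all_n <- out$pattern == strrep("N", 7L)
  out$status <- ifelse(all_n, "all_n",
                       ifelse(is.na(out$cluster), "unmapped", "mapped"))
  out
}

default_group_map <- function() {
  list(`1` = c(1L, 2L, 3L), `2` = c(5L, 7L, 9L), `3` = 10L, `4` = 15L,
       `5` = c(11L, 12L))
}

#' Select major clusters and assign groups
#'
#' Independently for up- and down-regulated genes, the selection
#' threshold is the `percentile` percentile (linear interpolation) of the
#' sizes of the catalogue clusters (absent clusters count as size 0);
#' clusters strictly larger than the threshold are flagged selected.
#' Groups follow the fixed map: Group 1 = clusters 1-3 (unique TF),
#' Group 2 = 5/7/9 (pairwise OR), Group 3 = 10 (triple AND), Group 4 = 15
#' (triple OR), Group 5 = 11-12 (mixed logics).
#'
#' @param clusters Result of [assign_clusters()].
#' @param percentile Size percentile (0-100) defining the threshold.
#' @param n_catalog Number of catalogue clusters over which sizes are
#'   tallied (15 for the conventional catalogue).
#' @param group_map Named list mapping group number to cluster indices.
#' @return `clusters` with added columns `group` (integer or NA) and
#'   `selected` (logical); attributes `"sizes"` (direction x cluster size
#'   table) and `"thresholds"` (per-direction threshold).
#' @export
cluster_select_group <- function(clusters, percentile = 50,
                                 n_catalog = 15L,
                                 group_map = default_group_map()) {
  cl2group <- rep(NA_integer_, 18L)
  for (g in names(group_map)) cl2group[group_map[[g]]] <- as.integer(g)
  sizes <- matrix(0L, nrow = 2L, ncol = n_catalog,
                  dimnames = list(c("U", "D"), seq_len(n_catalog)))
  mapped <- clusters$status == "mapped" & clusters$cluster <= n_catalog
  tab <- table(factor(clusters$direction[mapped], levels = c("U", "D")),
               factor(clusters$cluster[mapped], levels = seq_len(n_catalog)))
  sizes[] <- tab
  thresholds <- apply(sizes, 1L, stats::quantile, probs = percentile / 100,
                      type = 7)
  sel <- sizes > rep(thresholds, times = n_catalog)
  clusters$group <- ifelse(clusters$status == "mapped",
                           cl2group[clusters$cluster], NA_integer_)
  clusters$selected <- FALSE
  ok <- mapped
  clusters$selected[ok] <- sel[cbind(clusters$direction[ok],
                                     as.character(clusters$cluster[ok]))]
  attr(clusters, "sizes") <- sizes
  attr(clusters, "thresholds") <- thresholds
  clusters
}

#' Per-gene recovery of planted structures
#'
#' Compares an [assign_clusters()] table against a simulation truth
#' table: a planted gene is recovered when it maps to its planted cluster
#' with the direction its regulation mode implies (activated targets fall
#' in mutants, call D; repressed targets rise, call U).
#'
#' @param clusters An [assign_clusters()] result.
#' @param truth Truth table from [simulate_expression_study()].
#' @return List: `n_planted`, `n_recovered`, `recovery` (fraction),
#'   `structures_recovered` (distinct planted clusters found among the
#'   planted genes' mappings), `structures_mapped` (distinct clusters
#'   among all mapped genes).
#' @export
structure_recovery <- function(clusters, truth) {
  planted <- truth[!is.na(truth$cluster), , drop = FALSE]
  ix <- match(planted$gene_id, clusters$gene_id)
  got <- clusters[ix, , drop = FALSE]
  want_dir <- ifelse(planted$direction == "activated", "D", "U")
  hit <- !is.na(got$cluster) & got$cluster == planted$cluster &
    got$direction == want_dir
  list(n_planted = nrow(planted),
       n_recovered = sum(hit),
       recovery = if (nrow(planted) > 0) mean(hit) else NA_real_,
       structures_recovered = sort(unique(got$cluster[hit])),
       structures_mapped =
         sort(unique(clusters$cluster[clusters$status == "mapped"])))
}
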