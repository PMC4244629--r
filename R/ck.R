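# Classification of exogenous cytokinin responses against the
# mutant-derived regulatory structure.

#' Classify CK-responsive genes against the mutant regulatory structure
#'
#' Each gene called U or D in the CK comparison (WT + CK versus
#' WT + mock) is labelled by its direction in the deletion mutants: the
#' mapped cluster's direction when the gene sits in a regulatory
#' cluster, otherwise - for genes that are DEGs in some mutant but could
#' not be mapped to a structure - the dominant direction across the seven
#' mutant comparisons (direction ties are excluded and reported).  The
#' class is the pair of directions (`up_dw` = up under CK, down in
#' mutants, etc., `ck_only` when no mutant call exists), and genes in a
#' selected, group-assigned cluster carry the group suffix (e.g.
#' `up_dwG2`); all other mutant DEGs are `Others`.
#'
#' @param ck_degs DEG table of the CK comparison (from [deg_test()] /
#'   [deg_analysis()]).
#' @param clusters A [cluster_select_group()] table over the same gene
#'   universe.
#' @param patterns Optional [encode_patterns()] table supplying per-
#'   comparison mutant calls for the dominant-direction fallback.
#' @return List with elements `table` (per-gene: `gene_id`, `ck_call`,
#'   `mutant_direction`, `class`, `group_label`, `label`), `summary`
#'   (counts per label), `by_cluster` (counts per label and cluster) and
#'   `excluded` (genes dropped for tied mutant directions).
#' @export
classify_ck_overlap <- function(ck_degs, clusters, patterns = NULL) {
  stopifnot(all(c("gene_id", "call") %in% names(ck_degs)))
  if (anyDuplicated(clusters$gene_id))
    stop("cluster table has duplicated gene rows")
  ck <- ck_degs[ck_degs$call %in% c("U", "D"), , drop = FALSE]
  ix <- match(ck$gene_id, clusters$gene_id)
  cl <- clusters[ix, , drop = FALSE]

  mut_dir <- ifelse(!is.na(cl$cluster), cl$direction, NA_character_)
  dropped <- rep(FALSE, nrow(ck))
  if (!is.null(patterns)) {
    cmp <- arr_comparisons()
    pix <- match(ck$gene_id, patterns$gene_id)
    calls <- as.matrix(patterns[pix, cmp, drop = FALSE])
    n_u <- rowSums(calls == "U", na.rm = TRUE)
    n_d <- rowSums(calls == "D", na.rm = TRUE)
    fall <- is.na(mut_dir) & (n_u + n_d) > 0
    tie <- fall & n_u == n_d
    mut_dir[fall & n_u > n_d] <- "U"
    mut_dir[fall & n_d > n_u] <- "D"
    dropped <- tie
  }
  excluded <- ck$gene_id[dropped]
  keep <- !dropped
  ck <- ck[keep, , drop = FALSE]
  cl <- cl[keep, , drop = FALSE]
  mut_dir <- mut_dir[keep]

  ck_tag <- ifelse(ck$call == "U", "up", "dw")
  mut_tag <- ifelse(is.na(mut_dir), NA_character_,
                    ifelse(mut_dir == "U", "up", "dw"))
  class <- ifelse(is.na(mut_tag), "ck_only", paste0(ck_tag, "_", mut_tag))
  grouped <- !is.na(cl$cluster) & cl$selected & !is.na(cl$group)
  group_label <- ifelse(class == "ck_only", "",
                        ifelse(grouped, paste0("G", cl$group), "Others"))
  label <- paste0(class, ifelse(group_label == "Others", "_Others",
                                group_label))
  tab <- data.frame(gene_id = ck$gene_id, ck_call = ck$call,
                    mutant_direction = ifelse(is.na(mut_dir), "none",
                                              mut_dir),
                    cluster = cl$cluster, class = class,
                    group_label = group_label, label = label,
                    stringsAsFactors = FALSE)
  if (nrow(tab) > 0L) {
    summary <- as.data.frame(table(label = tab$label),
                             stringsAsFactors = FALSE)
    names(summary)[2] <- "n"
  } else {
    summary <- data.frame(label = character(0), n = integer(0),
                          stringsAsFactors = FALSE)
  }
  in_cl <- which(!is.na(tab$cluster))
  if (length(in_cl) > 0L) {
    by_cluster <- as.data.frame(table(label = tab$label[in_cl],
                                      cluster = tab$cluster[in_cl]),
                                stringsAsFactors = FALSE)
    names(by_cluster)[3] <- "n"
    by_cluster <- by_cluster[by_cluster$n > 0, , drop = FALSE]
    by_cluster$cluster <- as.integer(as.character(by_cluster$cluster))
    rownames(by_cluster) <- NULL
  } else {
    by_cluster <- data.frame(label = character(0), cluster = integer(0),
                             n = integer(0), stringsAsFactors = FALSE)
  }
  list(table = tab, summary = summary, by_cluster = by_cluster,
       excluded = excluded)
}
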