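# Integrative differential-expression statistic.
#
# Per gene and comparison: a pooled-variance Student t statistic (T) and a
# log2-median-ratio (M = median(test) - median(ref)).  Empirical null
# distributions for both are built by relabeling the comparison's samples
# (all balanced reassignments when few, seeded sampling otherwise) and
# pooling the permuted statistics across genes.  One-sided empirical
# p-values in the observed direction are combined with Stouffer's method,
# and a gene is called U/D only if the combined p passes alpha AND |M|
# exceeds the comparison-specific fold-change cutoff (a high quantile of
# the null |M| distribution).

row_medians <- function(x) {
  if (is.null(dim(x))) return(stats::median(x))
  if (ncol(x) == 2L) return(rowMeans(x))   # median of two = mean
  apply(x, 1L, stats::median)
}

#' Per-gene T statistic and log2-median-ratio
#'
#' Pooled-variance two-sample Student t (test minus reference) and the
#' difference of group medians on the log2 scale.  With zero pooled
#' variance T is 0 when the means agree and a signed infinity otherwise
#' (flagged via the `zero_variance` attribute).
#'
#' @param test,ref Numeric matrices (genes x samples) or vectors; each
#'   group needs >= 2 samples.
#' @return List with numeric vectors `t_stat` and `log2_median_ratio`.
#' @export
#' @examples
#' compute_gene_stats(c(2, 4), c(1, 3))   # t = 1/sqrt(2), M = 1
compute_gene_stats <- function(test, ref) {
  if (is.null(dim(test))) test <- matrix(test, nrow = 1L)
  if (is.null(dim(ref))) ref <- matrix(ref, nrow = 1L)
  n1 <- ncol(test); n2 <- ncol(ref)
  stopifnot(n1 >= 2L, n2 >= 2L, nrow(test) == nrow(ref))
  m1 <- rowMeans(test); m2 <- rowMeans(ref)
  v1 <- rowSums((test - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ref - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_stat <- ifelse(se > 0, diff / se,
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  out <- list(t_stat = unname(t_stat),
              log2_median_ratio = unname(row_medians(test) -
                                           row_medians(ref)))
  attr(out, "zero_variance") <- unname(se == 0 & diff != 0)
  out
}

#' Permutation null distributions for one comparison
#'
#' Relabels the comparison's samples: every distinct reassignment of
#' `n_test` of the pooled samples to the test group (excluding the
#' identity) when there are at most `max_perms`, otherwise a seeded
#' sample of distinct non-identity reassignments.  T and M are recomputed
#' per gene for each relabeling and pooled across genes and relabelings
#' into one common null per statistic.
#'
#' @param test,ref Numeric matrices (genes x samples) of the two groups.
#' @param max_perms Cap on the number of relabelings.
#' @param seed Optional seed (only consumed when sampling engages).
#' @return Object of class `deg_null`: list with `t_null`, `m_null`,
#'   `n_perms`, `scheme`.
#' @export
build_permutation_null <- function(test, ref, max_perms = 1000L,
                                   seed = NULL) {
  if (is.null(dim(test))) test <- matrix(test, nrow = 1L)
  if (is.null(dim(ref))) ref <- matrix(ref, nrow = 1L)
  n1 <- ncol(test); n2 <- ncol(ref); n <- n1 + n2
  x <- cbind(test, ref)
  combos <- utils::combn(n, n1)
  identity_col <- which(apply(combos, 2L, function(ix)
    all(ix == seq_len(n1))))
  combos <- combos[, -identity_col, drop = FALSE]
  if (ncol(combos) < 2L) stop("fewer than 2 distinct permutations")
  if (ncol(combos) > max_perms) {
    if (!is.null(seed)) set.seed(seed)
    combos <- combos[, sample(ncol(combos), max_perms), drop = FALSE]
  }
  t_null <- vector("list", ncol(combos))
  m_null <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    ix <- combos[, k]
    st <- compute_gene_stats(x[, ix, drop = FALSE],
                             x[, -ix, drop = FALSE])
    t_null[[k]] <- st$t_stat
    m_null[[k]] <- st$log2_median_ratio
  }
  structure(list(t_null = unlist(t_null), m_null = unlist(m_null),
                 n_perms = ncol(combos),
                 scheme = "within-comparison relabeling, pooled over genes"),
            class = "deg_null")
}

#' One-sided empirical p-value with add-one pseudocount
#'
#' For a positive observation, `p = (1 + #\{null >= obs\}) / (1 + N)`;
#' mirrored for a negative observation.  The pseudocount keeps p in
#' `[1/(N+1), 1]` so no gene gets p = 0 from a finite null.
#'
#' @param observed Numeric vector of observed statistics.
#' @param null_values Nonempty numeric vector of pooled null values.
#' @param side `"directional"` (default; side chosen by the sign of each
#'   observation), `"greater"`, or `"less"`.
#' @return Numeric vector of p-values.
#' @export
empirical_pvalue <- function(observed,
                             null_values,
                             side = c("directional", "greater", "less")) {
  side <- match.arg(side)
  if (length(null_values) == 0L) stop("empty null distribution")
  sn <- sort(null_values)
  n <- length(sn)
  n_ge <- n - findInterval(observed, sn, left.open = TRUE)  # #{null >= obs}
  n_le <- findInterval(observed, sn)                        # #{null <= obs}
  p_greater <- (1 + n_ge) / (1 + n)
  p_less <- (1 + n_le) / (1 + n)
  switch(side,
         greater = p_greater,
         less = p_less,
         directional = ifelse(observed >= 0, p_greater, p_less))
}

#' Stouffer combination of two p-values
#'
#' `z_i = qnorm(1 - p_i)`, `z_c = (z_t + z_m) / sqrt(2)`, combined
#' `p = 1 - pnorm(z_c)`.  Inputs are clamped to `[1e-15, 1 - 1e-15]` so
#' extremes never produce infinities.
#'
#' @param p_t,p_m Numeric vectors of p-values in (0, 1).
#' @return Numeric vector of combined p-values.
#' @export
#' @examples
#' stouffer_combine(0.05, 0.05)   # ~0.00999
stouffer_combine <- function(p_t, p_m) {
  clamp <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
  z <- (stats::qnorm(1 - clamp(p_t)) + stats::qnorm(1 - clamp(p_m))) /
    sqrt(2)
  1 - stats::pnorm(z)
}

#' Dual-gate DEG calls for one comparison
#'
#' Computes empirical p-values for T and M against the comparison's
#' permutation null, combines them with Stouffer's method, derives the
#' comparison-specific fold-change cutoff as the `fc_quantile` quantile
#' (linear interpolation) of the null |M| distribution, and calls a gene
#' U or D only when `p_combined <= alpha` AND `|M| >= fc_cutoff`;
#' otherwise N.  Direction is the sign of M.
#'
#' @param stats Result of [compute_gene_stats()] for the observed groups.
#' @param null A [build_permutation_null()] result for the same
#'   comparison.
#' @param genes Gene IDs (same order as the statistic vectors).
#' @param alpha Combined-p threshold.
#' @param fc_quantile Quantile of null |M| defining the fold-change
#'   cutoff.
#' @return Data frame with columns `gene_id`, `t_stat`,
#'   `log2_median_ratio`, `p_t`, `p_m`, `p_combined`, `bh_q` (BH-adjusted
#'   combined p, informational), `fc_cutoff`, `call`.
#' @export
call_degs <- function(stats, null, genes = NULL, alpha = 0.05,
                      fc_quantile = 0.95) {
  stopifnot(inherits(null, "deg_null"))
  t_stat <- stats$t_stat
  m <- stats$log2_median_ratio
  if (is.null(genes)) genes <- sprintf("g%05d", seq_along(t_stat))
  p_t <- empirical_pvalue(t_stat, null$t_null)
  p_m <- empirical_pvalue(m, null$m_null)
  p_c <- stouffer_combine(p_t, p_m)
  fc_cutoff <- unname(stats::quantile(abs(null$m_null), fc_quantile,
                                      type = 7))
  pass <- p_c <= alpha & abs(m) >= fc_cutoff & m != 0
  call <- ifelse(pass & m > 0, "U", ifelse(pass & m < 0, "D", "N"))
  data.frame(gene_id = genes, t_stat = t_stat, log2_median_ratio = m,
             p_t = p_t, p_m = p_m, p_combined = p_c,
             bh_q = stats::p.adjust(p_c, "BH"),
             fc_cutoff = fc_cutoff, call = call,
             stringsAsFactors = FALSE)
}

# sample IDs of a genotype/treatment condition
condition_samples <- function(study, genotype, treatment = "none") {
  s <- study$samples
  s$sample_id[s$genotype == genotype & s$treatment == treatment]
}

#' DEG test for a single comparison
#'
#' Convenience wrapper selecting the two groups from a study, building the
#' permutation null and applying the dual-gate call.
#'
#' @param study An [expression_study()].
#' @param test_genotype,ref_genotype Genotype labels of test and
#'   reference groups.
#' @param test_treatment,ref_treatment Treatments selecting the groups.
#' @param alpha,fc_quantile,max_perms See [call_degs()] and
#'   [build_permutation_null()].
#' @param seed Seed for permutation sampling.
#' @return A [call_degs()] data frame; the null is attached as attribute
#'   `"null"`.
#' @export
deg_test <- function(study, test_genotype, ref_genotype = "WT",
                     test_treatment = "none", ref_treatment = "none",
                     alpha = 0.05, fc_quantile = 0.95, max_perms = 1000L,
                     seed = NULL) {
  test_ids <- condition_samples(study, test_genotype, test_treatment)
  ref_ids <- condition_samples(study, ref_genotype, ref_treatment)
  if (length(test_ids) < 2L || length(ref_ids) < 2L)
    stop("each group needs >= 2 samples (",
         test_genotype, "/", test_treatment, " vs ",
         ref_genotype, "/", ref_treatment, ")")
  test <- study$exprs[, test_ids, drop = FALSE]
  ref <- study$exprs[, ref_ids, drop = FALSE]
  st <- compute_gene_stats(test, ref)
  null <- build_permutation_null(test, ref, max_perms = max_perms,
                                 seed = seed)
  out <- call_degs(st, null, genes = rownames(study$exprs), alpha = alpha,
                   fc_quantile = fc_quantile)
  attr(out, "null") <- null
  out
}

#' DEG analysis over all comparisons of the deletion design
#'
#' Runs [deg_test()] for each of the seven mutant-versus-wild-type
#' comparisons (untreated samples, canonical order) and, when the study
#' contains wild-type mock and CK samples, the CK comparison
#' (WT + CK versus WT + mock).
#'
#' @inheritParams deg_test
#' @param include_ck Run the CK comparison when its samples are present.
#' @return Named list of DEG tables, class `deg_analysis`; mutant
#'   comparisons are named by genotype (`"arr1"`, ..., `"arr1/10/12"`)
#'   and the treatment comparison `"CK"`.
#' @export
deg_analysis <- function(study, alpha = 0.05, fc_quantile = 0.95,
                         max_perms = 1000L, seed = 1L, include_ck = TRUE) {
  out <- list()
  for (i in seq_along(arr_comparisons())) {
    g <- arr_comparisons()[i]
    out[[g]] <- deg_test(study, g, alpha = alpha,
                         fc_quantile = fc_quantile, max_perms = max_perms,
                         seed = child_seed(seed, i))
  }
  if (include_ck &&
      length(condition_samples(study, "WT", "CK")) >= 2L &&
      length(condition_samples(study, "WT", "mock")) >= 2L) {
    out[["CK"]] <- deg_test(study, "WT", "WT", test_treatment = "CK",
                            ref_treatment = "mock", alpha = alpha,
                            fc_quantile = fc_quantile,
                            max_perms = max_perms,
                            seed = child_seed(seed, 8L))
  }
  class(out) <- "deg_analysis"
  out
}

#' @export
print.deg_analysis <- function(x, ...) {
  counts <- t(vapply(x, function(tab)
    c(U = sum(tab$call == "U"), D = sum(tab$call == "D")),
    numeric(2)))
  cat("deg_analysis over", length(x), "comparisons\n")
  print(data.frame(comparison = rownames(counts), up = counts[, "U"],
                   down = counts[, "D"],
                   total = counts[, "U"] + counts[, "D"],
                   row.names = NULL))
  invisible(x)
}

#' Write per-comparison DEG tables to TSV
#'
#' @param degs A `deg_analysis` list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_deg_tables <- function(degs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(degs)) {
    p <- file.path(dir, paste0("deg_", gsub("/", "-", nm, fixed = TRUE),
                               ".tsv"))
    utils::write.table(degs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
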