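# Expression-study container, TSV round-trip, quantile normalization and
# probe-to-gene collapsing.

#' Expression study container
#'
#' Bundles a genes-by-samples log2-intensity matrix with its sample sheet
#' and validates the design: every matrix column must be described exactly
#' once, genotypes must be one of the eight valid labels and treatments
#' one of none/mock/CK.
#'
#' @param exprs Numeric matrix, rows = genes/probes, columns = samples
#'   (column names = sample IDs).
#' @param samples Data frame with columns `sample_id`, `genotype`,
#'   `treatment`, `replicate`.
#' @param allow_na Permit missing values (default FALSE; most downstream
#'   stages require complete data).
#' @return An object of class `expression_study`: a list with elements
#'   `exprs` and `samples`.
#' @export
expression_study <- function(exprs, samples, allow_na = FALSE) {
  exprs <- as.matrix(exprs)
  if (nrow(exprs) == 0L || ncol(exprs) == 0L) stop("empty expression matrix")
  if (!is.numeric(exprs)) stop("expression matrix must be numeric")
  if (!allow_na && anyNA(exprs)) stop("expression matrix contains NA values")
  req <- c("sample_id", "genotype", "treatment", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (is.null(colnames(exprs))) stop("expression matrix needs column names")
  missing <- setdiff(colnames(exprs), samples$sample_id)
  if (length(missing) > 0L)
    stop("sample sheet missing metadata for sample(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  samples <- samples[match(colnames(exprs), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad_gt <- setdiff(unique(samples$genotype), arr_genotypes())
  if (length(bad_gt) > 0L)
    stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "))
  bad_tr <- setdiff(unique(samples$treatment), arr_treatments())
  if (length(bad_tr) > 0L)
    stop("unknown treatment label(s): ", paste(bad_tr, collapse = ", "))
  structure(list(exprs = exprs, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$exprs), "genes x", ncol(x$exprs),
      "samples\n")
  tab <- table(x$samples$genotype, x$samples$treatment)
  print(tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE])
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV with a header row of sample IDs and gene IDs in
#'   the first column (duplicate gene IDs allowed; collapse later with
#'   [collapse_probes()]).
#' @param sheet_path TSV sample sheet with columns `sample_id`,
#'   `genotype`, `treatment`, `replicate`.
#' @param missing `"error"` (default) rejects missing values; `"drop"`
#'   removes rows containing any NA.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(matrix_path, sheet_path,
                                  missing = c("error", "drop")) {
  missing <- match.arg(missing)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in expression matrix")
  rownames(mat) <- ids
  if (missing == "drop") mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  expression_study(mat, sheet)
}

#' Write an expression study to TSV files
#'
#' @param study An [expression_study()].
#' @param matrix_path,sheet_path Output paths (sheet omitted if NULL).
#' @return Invisibly, `study`.
#' @export
write_expression_study <- function(study, matrix_path, sheet_path = NULL) {
  df <- data.frame(gene_id = rownames(study$exprs), study$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sheet_path))
    utils::write.table(study$samples, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(study)
}

#' Read the table section of a GEO series matrix file
#'
#' Minimal reader for the plain-text SOFT-style series matrix format: the
#' block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` is parsed as a TSV with probe IDs in the
#' first column.
#'
#' @param path Path to an (uncompressed) series matrix file.
#' @return Numeric matrix, rows = probes, columns = samples.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("no series matrix table section found")
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- gsub('"', "", as.character(tab[[1L]]))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- ids
  mat
}

#' Quantile normalization
#'
#' Forces every sample to share one reference distribution: the vector of
#' row means of the column-sorted matrix.  Tied values within a column
#' receive the mean of the reference quantiles they span.  Row order is
#' preserved and the operation is idempotent.
#'
#' @param x An [expression_study()] or a numeric matrix (>= 2 columns, no
#'   missing values).
#' @return Same class as the input, with normalized intensities.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x) UseMethod("quantile_normalize")

#' @export
quantile_normalize.matrix <- function(x) {
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x)) stop("missing values; apply a missing-value policy first")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
quantile_normalize.expression_study <- function(x) {
  x$exprs <- quantile_normalize.matrix(x$exprs)
  x
}

#' Collapse probes to genes
#'
#' Per-gene median across that gene's probes, per sample.  Applied after
#' normalization; invariant to probe order.
#'
#' @param study An [expression_study()] whose rows are probes.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`
#'   covering every matrix row.
#' @return An [expression_study()] with one row per gene.
#' @export
collapse_probes <- function(study, probe_map) {
  stopifnot(inherits(study, "expression_study"),
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  idx <- match(rownames(study$exprs), probe_map$probe_id)
  if (anyNA(idx)) stop("probe_map does not cover all probes")
  gene <- factor(probe_map$gene_id[idx],
                 levels = unique(probe_map$gene_id[idx]))
  collapsed <- apply(study$exprs, 2L, function(col)
    tapply(col, gene, stats::median))
  collapsed <- as.matrix(collapsed)
  rownames(collapsed) <- levels(gene)
  expression_study(collapsed, study$samples)
}
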