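# Gene-set over-representation: one-tailed hypergeometric (Fisher) test
# with an optional EASE-style conservative variant (overlap reduced by
# one before testing).

#' Hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the overlap between query and term within the universe.  The
#' EASE variant recomputes the tail after removing one gene from the
#' overlap (floor 0), which penalises small overlaps the way the
#' EASE score of annotation-enrichment tools does.  A BH-adjusted column is included for transparency;
#' the `passes` flag uses the raw p of the chosen variant against
#' `threshold`.
#'
#' @param query Character vector of query gene IDs (subset of
#'   `universe`).
#' @param annotation Named list of term gene sets (see [read_gmt()]).
#' @param universe Character vector: the gene universe (e.g. all genes on
#'   the platform).
#' @param variant `"fisher"` (default) or `"ease"`: which p-value drives
#'   sorting and the `passes` flag.
#' @param threshold Raw p-value cutoff for `passes`.
#' @return Data frame sorted by the variant p: `term`, `overlap`,
#'   `query_size`, `term_size`, `universe_size`, `p`, `ease_p`, `bh_q`,
#'   `passes`.
#' @export
#' @examples
#' fisher_enrichment(letters[1:5], list(t1 = letters[1:5]), letters[1:20])
fisher_enrichment <- function(query, annotation, universe,
                              variant = c("fisher", "ease"),
                              threshold = 0.1) {
  variant <- match.arg(variant)
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe)) stop("query must be a subset of universe")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(annotation), function(term) {
    members <- unique(intersect(annotation[[term]], universe))
    k <- length(intersect(query, members))
    m <- length(members)
    p <- stats::phyper(k - 1, m, n_u - m, n_q, lower.tail = FALSE)
    ease_k <- max(k - 1L, 0L)
    ease_p <- stats::phyper(ease_k - 1, m, n_u - m, n_q,
                            lower.tail = FALSE)
    data.frame(term = term, overlap = k, query_size = n_q, term_size = m,
               universe_size = n_u, p = p, ease_p = ease_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(
    term = character(0), overlap = integer(0), query_size = integer(0),
    term_size = integer(0), universe_size = integer(0), p = numeric(0),
    ease_p = numeric(0), bh_q = numeric(0), passes = logical(0)))
  out$bh_q <- stats::p.adjust(out$p, "BH")
  p_used <- if (variant == "ease") out$ease_p else out$p
  out$passes <- p_used < threshold
  out[order(p_used), , drop = FALSE]
}

#' Read a GMT annotation file
#'
#' Standard GMT: term, description, then gene IDs, tab-separated.
#'
#' @param path Input path.
#' @return Named list of gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write annotation sets to GMT
#'
#' @param sets Named list of gene-ID vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
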