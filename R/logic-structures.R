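# Enumeration and algebra of monotone Boolean regulatory structures.
#
# A regulatory structure is a non-constant monotone Boolean function over
# presence of the regulators, represented canonically as the antichain of
# its minimal sufficient regulator subsets (minimal DNF).  For three
# regulators there are exactly 18 such functions (the 20 monotone functions
# minus the two constants).  Deleting a regulator set S switches a
# structure off precisely when S intersects every minimal sufficient
# subset (the hitting-set criterion), which yields the predicted set of
# changed comparisons.

# canonical cluster numbering over antichain signatures (bitmask terms,
# sorted ascending, comma-joined); C1-C15 follow the conventional cluster
# order, 16-18 are the three x AND (y OR z) forms observed in no cluster
.structure_order3 <- c(
  "1" = 1L, "2" = 2L, "4" = 3L, "3" = 4L, "1,2" = 5L, "5" = 6L,
  "1,4" = 7L, "6" = 8L, "2,4" = 9L, "7" = 10L, "3,5,6" = 11L,
  "1,6" = 12L, "2,5" = 13L, "3,4" = 14L, "1,2,4" = 15L,
  "3,5" = 16L, "3,6" = 17L, "5,6" = 18L)

# explicit factored labels where minimal-DNF spelling is not the
# conventional one
.structure_labels3 <- c(
  `3,5` = "1&(10|12)", `3,6` = "10&(1|12)", `5,6` = "12&(1|10)")

bit_names <- function(mask, tf_names) {
  n <- length(tf_names)
  tf_names[bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L]
}

label_antichain <- function(masks, tf_names) {
  sig <- paste(sort(masks), collapse = ",")
  if (length(tf_names) == 3L && sig %in% names(.structure_labels3)) {
    return(unname(.structure_labels3[sig]))
  }
  n_bits <- vapply(masks, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L),
                   integer(1))
  ordered <- masks[order(n_bits, masks)]   # singleton terms first
  terms <- vapply(ordered, function(m) {
    tfs <- bit_names(m, tf_names)
    term <- paste(tfs, collapse = "&")
    if (length(tfs) > 1L && length(masks) > 1L) paste0("(", term, ")")
    else term
  }, character(1))
  paste(terms, collapse = "|")
}

#' Enumerate all monotone Boolean regulatory structures
#'
#' Brute-force enumeration over all truth tables on `n_tfs` regulators,
#' keeping the non-constant monotone functions and reducing each to its
#' antichain of minimal sufficient regulator subsets.  For three
#' regulators this yields exactly 18 structures; the first 15 carry the
#' conventional cluster numbering C1-C15 (C1 = "1", ..., C10 = "1&10&12",
#' C15 = "1|10|12") and 16-18 are the three `x&(y|z)` forms.
#'
#' @param n_tfs Number of regulators (1 to 4; the package's analysis uses
#'   3).
#' @param tf_names Display names of the regulators; defaults to
#'   `c("1","10","12")` for `n_tfs = 3` (the ARR1/10/12 convention).
#' @return A list of structures, each a list with elements `index`
#'   (canonical cluster number), `label` (e.g. `"1|(10&12)"`, `&` = AND,
#'   `|` = OR), `antichain` (list of character vectors of regulator
#'   names), `masks` (integer bitmasks of the antichain), and `changed`
#'   (integer deletion bitmasks whose deletion switches the structure
#'   off).  Ordered by `index`.
#' @export
#' @examples
#' cat3 <- enumerate_structures(3)
#' length(cat3)            # 18
#' cat3[[7]]$label         # "1|12"
enumerate_structures <- function(n_tfs = 3L,
                                 tf_names = NULL) {
  stopifnot(n_tfs >= 1L, n_tfs <= 4L)
  n_tfs <- as.integer(n_tfs)
  if (is.null(tf_names)) {
    tf_names <- if (n_tfs == 3L) ARR_TF_NAMES else as.character(seq_len(n_tfs))
  }
  stopifnot(length(tf_names) == n_tfs)
  n_pts <- 2L^n_tfs
  pts <- 0:(n_pts - 1L)
  # subset_of[a+1, b+1] <- a is a subset of b (as bitmasks)
  subset_of <- outer(pts, pts, function(a, b) bitwAnd(a, b) == a)
  out <- list()
  for (code in 0:(2L^n_pts - 1L)) {
    f <- as.integer(intToBits(code))[seq_len(n_pts)]
    if (all(f == 0L) || all(f == 1L)) next
    if (any(subset_of & outer(f, f, `>`))) next   # not monotone
    true_pts <- pts[f == 1L]
    minimal <- true_pts[vapply(true_pts, function(p) {
      !any(true_pts != p & subset_of[true_pts + 1L, p + 1L])
    }, logical(1))]
    full <- n_pts - 1L
    changed <- setdiff(pts, 0L)
    changed <- changed[f[full - changed + 1L] == 0L]
    out[[length(out) + 1L]] <- list(
      label = label_antichain(minimal, tf_names),
      antichain = lapply(sort(minimal), bit_names, tf_names = tf_names),
      masks = sort(minimal),
      changed = sort(changed))
  }
  sigs <- vapply(out, function(s) paste(s$masks, collapse = ","), character(1))
  if (n_tfs == 3L) {
    idx <- unname(.structure_order3[sigs])
    stopifnot(!anyNA(idx))
  } else {
    idx <- order(order(lengths(lapply(out, `[[`, "changed")), sigs))
  }
  for (i in seq_along(out)) out[[i]]$index <- idx[i]
  out[order(idx)]
}

#' Predicted changed-comparison set of a structure
#'
#' A deletion set switches a monotone structure off exactly when it
#' intersects every minimal sufficient regulator subset.  For the
#' structure `1|12` (either ARR1 or ARR12 suffices) the only deletions
#' that abolish regulation are those removing both, i.e. arr1/12 and the
#' triple mutant.
#'
#' @param structure A structure as returned by [enumerate_structures()],
#'   or a list/vector of antichain bitmasks.
#' @param n_tfs Number of regulators (used when a bare mask vector is
#'   given).
#' @return Sorted integer vector of deletion bitmasks.
#' @export
#' @examples
#' s <- enumerate_structures(3)[[7]]     # 1|12
#' predict_changed_set(s)                # masks 5 (arr1/12) and 7 (triple)
predict_changed_set <- function(structure, n_tfs = 3L) {
  masks <- if (is.list(structure) && !is.null(structure$masks)) {
    structure$masks
  } else {
    as.integer(unlist(structure))
  }
  stopifnot(length(masks) >= 1L, all(masks >= 1L))
  cand <- 1:(2L^n_tfs - 1L)
  hits <- vapply(cand, function(S) all(bitwAnd(S, masks) > 0L), logical(1))
  sort(cand[hits])
}

#' Structure catalogue as a data frame
#'
#' Flat view of [enumerate_structures()] with the predicted changed
#' comparisons spelled as genotype labels, convenient for joining against
#' cluster tables and for export.
#'
#' @param restrict `"all18"` (default) or `"core15"` to drop the three
#'   `x&(y|z)` structures outside the conventional 15-cluster catalogue.
#' @return A data frame with columns `cluster`, `label`, `changed_masks`
#'   (comma-joined bitmasks) and `changed_genotypes`.
#' @export
structure_catalog <- function(restrict = c("all18", "core15")) {
  restrict <- match.arg(restrict)
  cat3 <- enumerate_structures(3L)
  if (restrict == "core15") cat3 <- cat3[seq_len(15L)]
  data.frame(
    cluster = vapply(cat3, `[[`, integer(1), "index"),
    label = vapply(cat3, `[[`, character(1), "label"),
    changed_masks = vapply(cat3, function(s)
      paste(s$changed, collapse = ","), character(1)),
    changed_genotypes = vapply(cat3, function(s)
      paste(mask_to_genotype(s$changed), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

# superset closure of a set of deletion masks on the 3-TF lattice:
# if deleting S changes the gene then so does deleting any superset of S
closure_masks <- function(masks, n_tfs = 3L) {
  if (length(masks) == 0L) return(integer(0))
  cand <- 1:(2L^n_tfs - 1L)
  keep <- vapply(cand, function(S)
    any(bitwAnd(S, masks) == masks), logical(1))
  sort(cand[keep])
}
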