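# Genotype and comparison bookkeeping shared by all stages.
#
# The three regulators are encoded as bits (ARR1 = 1, ARR10 = 2, ARR12 = 4)
# so a deletion genotype is the bitmask of the deleted regulators and the
# wild type is mask 0.  All pattern/logic code works on these masks.

ARR_TF_NAMES <- c("1", "10", "12")
ARR_TF_BITS <- c(`1` = 1L, `10` = 2L, `12` = 4L)

#' Valid genotype labels
#'
#' The eight genotypes of the combinatorial deletion design: wild type plus
#' every nonempty subset of \{ARR1, ARR10, ARR12\} deleted.
#'
#' @return Character vector of the eight genotype labels in canonical order
#'   (WT, singles, doubles, triple).
#' @export
#' @examples
#' arr_genotypes()
arr_genotypes <- function() {
  c("WT", "arr1", "arr10", "arr12", "arr1/10", "arr1/12", "arr10/12",
    "arr1/10/12")
}

# deletion bitmask per genotype, same order as arr_genotypes()
genotype_masks <- function() {
  c(WT = 0L, arr1 = 1L, arr10 = 2L, arr12 = 4L, `arr1/10` = 3L,
    `arr1/12` = 5L, `arr10/12` = 6L, `arr1/10/12` = 7L)
}

#' Canonical mutant comparison order
#'
#' The seven mutant-versus-wild-type comparisons in the fixed order used
#' throughout: the three singles, the three doubles, then the triple.
#'
#' @return Character vector of the seven mutant genotype labels.
#' @export
arr_comparisons <- function() {
  arr_genotypes()[-1L]
}

# deletion masks for the seven comparisons, canonical order
comparison_masks <- function() {
  unname(genotype_masks()[arr_comparisons()])
}

arr_treatments <- function() c("none", "mock", "CK")

# label for a deletion bitmask, e.g. 5 -> "arr1/10/12"[no] -> "arr1/12"
mask_to_genotype <- function(mask) {
  gm <- genotype_masks()
  names(gm)[match(mask, gm)]
}

# per-comparison seeds derived from one pipeline seed; keeps every stage
# independently reproducible while staying inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147480000 + 7919 * k) %% 2147483647)
}
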