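Package: arrlogic
Title: Boolean Regulatory Logic from Combinatorial Knockout Expression
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers AND/OR transcriptional regulatory structures of
    duplicated transcription factors from expression profiles of wild type
    and all deletion-mutant combinations, modelled on the three type-B
    cytokinin response regulators ARR1, ARR10 and ARR12 of Arabidopsis
    roots.  Provides an integrative differential-expression statistic
    (pooled t and log2-median-ratio against permutation nulls, combined
    with Stouffer's method and a dual significance/fold-change gate),
    enumeration of all monotone Boolean regulatory structures over three
    regulators, mapping of per-gene up/down/no-change patterns onto those
    structures, empirical-null hub and clustering-coefficient analysis of
    interaction networks, hypergeometric (Fisher/EASE) gene-set
    enrichment, and classification of exogenous cytokinin responses
    against the inferred structures.  A seeded synthetic-data generator
    with planted logic structures makes the whole pipeline testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
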