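Package: wgcnam
Title: Weighted Gene Co-Expression Networks with Modularity Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from normalized
    expression matrices (Pearson correlation raised to a soft-threshold power
    chosen by the scale-free topology criterion, followed by hard edge
    thresholding) and detects modules by greedy maximization of weighted
    modularity or modularity density. Includes permutation tests for the
    significance of the modular structure, Rand-index comparison of gene
    partitions with an unassigned-as-singletons convention, combination and
    FDR/fold-change filtering of differential-expression tables, an FDR-sweep
    procedure for choosing the feature-selection cutoff, and a synthetic-data
    generator (planted co-expression modules, negative-binomial counts) so the
    whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
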