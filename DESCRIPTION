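Package: netpreserve
Title: Differential Module Preservation in Weighted Gene Coexpression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds signed weighted gene coexpression networks for a reference
    condition and two test conditions, detects coexpression modules in the
    reference network by average-linkage clustering of topological overlap
    with a dynamic tree cut, quantifies the preservation of each reference
    module in the test networks with permutation-based density and
    connectivity Z statistics aggregated into Z_summary, and scores
    differential preservation between the two test networks via the
    difference of Z_summary scores with gain/loss-of-preservation calls.
    Includes the surrounding preprocessing chain (probe summarization,
    low-abundance filtering, normalization, empirical-Bayes batch correction,
    covariate adjustment, sample outlier removal, PCA quality control) and a
    seeded synthetic-data generator with planted latent-factor modules,
    batch effects and covariates for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    sva,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
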