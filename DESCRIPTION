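Package: mcdmk
Title: Estimating the Number of Clusters by Multi-Criteria Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the number of clusters in a numeric data set by
    treating candidate cluster counts as decision alternatives. A k-means
    sweep over a candidate range is scored with ten relative cluster
    validity indices (Hubert Gamma, normalized Hubert Gamma, Dunn,
    Davies-Bouldin, CS, SD, S_Dbw, silhouette, PBM, C-index), and the
    candidates are ranked with three multi-criteria decision making
    methods: the weighted sum model (WSM), PROMETHEE II net outranking
    flows, and TOPSIS closeness to the ideal solution. Criterion weights
    can be uniform or elicited from expert scores. Includes a synthetic
    Gaussian-mixture generator for benchmarking, close-tie reporting for
    near-equal rankings, and summarizers for multi-dataset evaluations.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    foreign,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
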