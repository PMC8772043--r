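Package: dgrn
Title: Biomarker Discovery from Gene Regulatory Network Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs condition-specific gene regulatory networks by pruning
    a prior background network with conditional-mutual-information based
    path-consistency testing, extracts the differential (rewired) network
    between two phenotypes, partitions it into modules by greedy modularity
    maximization, and selects per-module biomarker gene panels with
    L2-regularized logistic regression and recursive feature elimination under
    cross-validation. Includes a linear-Gaussian structural-equation simulator
    with planted rewiring for end-to-end recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
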