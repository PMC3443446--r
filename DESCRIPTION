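Package: coexdiff
Title: Differential Topology of Gene Coexpression Networks Across Radiation Doses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Staged analysis of dose-dependent transcriptional response via
    gene coexpression network topology: generalized-log (glog) variance
    stabilization with maximum-likelihood parameter estimation, quantile
    normalization, detection-p-value probe filtering, per-gene cell-means
    ANOVA with dose-versus-control contrasts and Benjamini-Hochberg FDR,
    rank/threshold coexpression network construction, and cross-network
    comparison by per-gene topological overlap, a degree-preserving
    rewiring null model, and differential connectivity. Includes a
    synthetic microarray generator (two-component intensity error model,
    planted differential expression, planted dose-specific coexpression
    modules) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
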