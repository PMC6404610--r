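Package: coexstab
Title: Stability-Filtered Gene Coexpression Networks for Evolved
    Expression Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds signed weighted gene coexpression networks from bulk
    RNA-seq count data and filters module membership by replicate
    resampling: modules are reconstructed on repeatedly subsampled
    replicate sets, genes are retained only when they consistently fall
    in well-supported groups of their module, correlated module
    eigengenes are merged and undersized modules dissolved. Module
    eigengenes are then classified into reaction-norm categories (shared
    plasticity, divergent baseline, evolved or divergent plasticity,
    non-plastic divergence) from two-way ANOVA across environments and
    selected populations, with Tukey HSD letters for population
    contrasts.  Also provides median-of-ratios normalisation, a
    variance-stabilising transform, residual-SVD surrogate-variable
    removal, Bray-Curtis ordination with non-metric multidimensional
    scaling and PERMANOVA, one-tailed Fisher gene-set enrichment with
    Benjamini-Hochberg control, and a negative-binomial count simulator
    with planted modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    DESeq2,
    fgsea,
    igraph,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
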