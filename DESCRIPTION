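Package: mtgrn
Title: Multi-Task Inference of Cell Type-Specific Gene Regulatory Networks on Cell Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint inference of cell type-specific gene regulatory networks for cell
    types related by a lineage tree, from per-cell-type single-cell expression
    matrices. Each network is a dependency network with conditional-Gaussian
    pseudo-likelihood; a per-edge Markov chain over the lineage tree shares
    structure between related cell types and a logistic prior integrates
    accessibility/motif-derived edge weights. Includes stability selection for
    per-edge confidence scores, construction of prior networks from motif
    instances, accessibility peaks and TSS annotations, a linear-Gaussian
    lineage simulator with dropout sparsification, evaluation metrics (AUPR
    with Davis-Goadrich interpolation, F-score at K, predictable regulators),
    and dynamic-network analyses (k-means edge clustering with silhouette-based
    model selection, latent Dirichlet allocation topic networks, minimum
    spanning tree lineage recovery, hypergeometric gene-set enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
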