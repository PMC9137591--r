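Package: gutcooc
Title: Gut Microbiota Diversity, Composition Screening and Co-Occurrence
    Networks for Small Compartmentalised Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genus/OTU count tables from small,
    compartmentalised animal microbiome designs (two body-weight groups
    times three gut sampling places times few birds). Covers low-count
    feature filtering, rarefaction, alpha diversity (Chao1, Shannon,
    Simpson, Faith's PD), Bray-Curtis and chi-square beta diversity with
    PCoA, PERMANOVA, ANOSIM and CCA, two-way ANOVA composition screening
    with Benjamini-Hochberg FDR and Tukey letters, Spearman screening of
    genus abundance against individual body weight, and a co-occurrence
    network procedure built for five-sample groups: prevalence filtering,
    exact small-n Spearman p-values by permutation enumeration, edge
    calling at a rho threshold, and Monte Carlo significance of per-genus
    connection counts and of network components, including a bipartite
    lumen-mucosa variant. A Dirichlet-multinomial synthetic community
    generator with planted correlated blocks and planted body-weight
    effects provides ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    picante,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
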