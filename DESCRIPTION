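Package: pyronet
Title: Pyrodiversity and the Structure and Resistance of Plant-Pollinator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify pyrodiversity (Simpson's diversity of per-cell fire
    history categories within a buffer around a monitoring site) from stacks of
    burn-severity rasters, to build weighted bipartite plant-pollinator networks
    from visitation surveys, and to relate the two. Computes community-level
    network structure (Rao functional redundancy, dendrogram-based functional
    complementarity, mean-degree generalization), species-level network roles
    (centralities on the one-mode projection, Chao2 rarefied degree, Chao
    abundance-based niche overlap, Bluethgen d' specialization, species strength,
    and a PCA network-niche score), partner and niche flexibility (interaction
    beta-diversity as multivariate dispersion; coefficient of variation of the
    niche score across a landscape), co-extinction cascade robustness on observed
    and potential (re-wired) networks, and linear mixed models of community and
    population resistance to drought. Includes a synthetic-data generator that
    emulates the sampling design of a two-year, multi-site pollinator survey
    along a fire-history gradient so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
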