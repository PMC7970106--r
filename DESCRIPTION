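Package: crossomics
Title: Stepwise Multi-Omics Integration: Joint Components, Non-Parametric
    Combination, and Gene-Set Clustering
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A stepwise framework for integrating two preprocessed omics
    blocks measured on (partially) overlapping samples. Provides per-omic
    principal component exploration with metadata association tests;
    joint-and-individual low-rank decomposition of paired blocks with
    permutation-based and canonical-correlation-based model selection;
    permutation-driven non-parametric combination (Fisher, Liptak, Tippett)
    of per-omic evidence across gene-mapped feature tuples, including a
    whole-dataset permutation mode for partially overlapping samples and a
    fast parametric alternative; and gene-set-level summarisation via
    over-representation analysis, relative-risk similarity, and k-means
    clustering with gap-statistic model selection. Seeded generators create
    synthetic inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
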