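Package: phenoPAM
Title: Weighted Gower-PAM Clustering of Mixed Phenotype Data from Gene
    Knockout Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clustering of large-scale phenomics data for gene knockout
    collections in filamentous fungi, where each mutant is scored on a
    mixture of continuous traits (basal hyphal growth rate, aerial hyphae
    height) and categorical developmental traits (conidia, protoperithecia,
    perithecia and ascospore number and morphology). Implements weighted
    Gower dissimilarity and a deterministic Partitioning Around Medoids
    (PAM) algorithm for mixed data, cluster-quality statistics (per-cluster
    relative standard deviation and percent categorical consensus) with a
    weight-by-k model-selection scan, K-means profiling of expression time
    courses with within-sum-of-squares, gap-statistic and Davies-Bouldin
    diagnostics and a dominant-profile mapping onto phenotypic clusters,
    cluster-composition summaries against gene annotations, a chromosome
    goodness-of-fit test, and seeded synthetic-data generators with planted
    structure for end-to-end validation.
License: MIT + file LICENSE
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
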