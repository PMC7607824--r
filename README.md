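# phenoPAM

Clustering of large-scale phenotype data from gene-knockout collections
in filamentous fungi.

High-throughput phenotyping of *Neurospora crassa* knockout mutants
scores each strain on a mixture of trait types: two continuous traits
(basal hyphal growth rate in mm/day and aerial hyphae height in mm) and
eight categorical developmental traits (number and morphology of
conidia, protoperithecia, perithecia and ascospores). Grouping mutants
with similar trait profiles suggests shared pathway membership, but
ordinary clustering pipelines either discard the categorical traits or
force them onto an arbitrary numeric scale. `phenoPAM` implements a
mixed-data pipeline built around weighted Gower dissimilarity and
Partitioning Around Medoids (PAM), together with the quality statistics
needed to choose trait weights and the number of clusters, and the
downstream analyses that interpret the clusters.

## The method

**Dissimilarity.** For mutants *i*, *j* and trait weights *w*,

d(i,j) = Σ_t w_t δ_t(i,j) / Σ_t w_t

with δ_t = |x_i − x_j| / range_t for a continuous trait and
δ_t = 1{x_i ≠ x_j} for a categorical trait (labels treated as nominal).
Seven named weight presets are provided; preset `W6 =
(1,1,1,1,1,1,1,1,6,6)` up-weights the two continuous traits six-fold.

**Clustering.** A deterministic PAM (greedy BUILD, then repeated
best-improvement SWAP with smallest-index tie-breaks) minimizes
Σ_i d(i, medoid(i)) over k medoids. Ward (ward.D2) and complete-linkage
HAC on the same matrix, and seeded K-means (k-means++ initialization,
Lloyd iterations, best of several restarts) on numeric conversions, are
available for comparison.

**Model selection.** For every cluster the pipeline reports the relative
standard deviation of each continuous trait (100·SD/mean, per cent) and
the percent consensus of each categorical trait (share of the modal
label). Run-level per-trait averages (clusters weighted equally) are
condensed into two composites, and a run passes the guidelines when every
cluster has ≥ 3 genes, there are ≤ 40 clusters, composite relative SD
< 15 % and composite consensus ≥ 95 %. `weightScan()` tabulates these
over a weights × k grid.

**Expression mapping.** Expression time courses are row-standardized to
mean 0, SD 2, profiled with seeded K-means (with within-SS, gap-statistic
and Davies–Bouldin diagnostics for the number of profiles), and mapped
onto the phenotypic clusters: a profile is *dominant* in a cluster when
it covers ≥ 40 % of that cluster's expression-covered genes; clusters
with < 3 covered genes are excluded.

**Composition and genome tests.** `composition()` reports per-cluster
percentages of boolean gene attributes (yeast ortholog, transmembrane
domain, GPCR, kinase, phosphatase, phosphoprotein, MAPK-pathway
targets), `multiPathwayTargets()` counts genes targeted by one, two or
three MAPK pathways, and `chromosomeGof()` runs the Pearson chi-square
goodness-of-fit test of dataset-versus-genome gene counts across the
seven linkage groups.

Every stochastic stage takes an explicit seed, and seeded generators
(`simulatePhenotypes()`, `simulateExpression()`,
`simulateAnnotations()`) produce cohorts with planted structure so the
whole pipeline is testable without any downloads.

## Worked example

```r
library(phenoPAM)

# a synthetic cohort with 40 planted clusters (1168 mutants, the
# published cluster-size spectrum, consensus 0.95, SD = 5% of mean)
sim <- simulatePhenotypes(publishedCohortConfig(seed = 1))
tab <- filterComplete(sim$table)
#> filterComplete: retained 1168 complete records, dropped 0 incomplete

d   <- gowerMatrix(tab, "W6")
fit <- pamCluster(d, 40)
fit
#> ClusterAssignment: pam, k = 40, n = 1168, total cost = 38.2773
#>   cluster sizes: min 7, median 15, max 171

mclust::adjustedRandIndex(clusterLabels(fit), sim$labels[geneIds(fit)])
#> [1] 0.9525057

q <- runQuality(fit, tab)
q
#> QualityReport: pam, k = 40
#>   composite consensus: 94.38%  composite RSD: 5.17%

guidelineCheck(q)$pass      # consensus 94.4 < 95: the verdict reports it
#> [1] FALSE

head(clusterSummary(fit, tab)[, c("cluster", "size", "growth_rate",
                                  "aerial_height")], 3)
#>   cluster size  growth_rate         aerial_height
#> 1       1    9 100% Reduced       56% Normal High
#> 2       2   82 100% Reduced 100% Severely Reduced
#> 3       3    8 100% Reduced  88% Severely Reduced
```

The composite consensus of 94.38 % says that, averaged over the eight
categorical traits and the forty clusters, the modal phenotype covers
94 % of each cluster — close to the planted 95 % consensus — while the
5.2 % composite relative SD shows the continuous traits are tightly
grouped within clusters (5 % noise was planted). The adjusted Rand
index of 0.95 against the planted labels means the weighted-PAM run
recovered the planted structure almost exactly.

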