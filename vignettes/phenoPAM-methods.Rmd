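---
title: "Clustering mixed phenotype data with weighted Gower and PAM"
author: "phenoPAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering mixed phenotype data with weighted Gower and PAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data model

Gene-knockout collections in filamentous fungi are phenotyped on traits
of two kinds. Two are continuous measurements: basal hyphal growth rate
(mm/day; wild type 75--85) and aerial hyphae height (mm; wild type
30--45). Eight are categorical scores from visual screens: number and
morphology of conidia (asexual spores), protoperithecia and perithecia
(unfertilized and fertilized female sexual structures) and ascospores
(sexual spores). Abundance traits use a six-level severity vocabulary
(Not Formed, Severely Reduced, Reduced, Slightly Reduced, Normal,
Increased); morphology traits use Not Formed / Abnormal / Normal.
A mutant record is *complete* when all ten traits are present; only
complete records are clustered, because the dissimilarity below has no
missing-data variant and a partially scored strain would otherwise be
compared on a shifting subset of traits.

`PhenotypeTable` carries the records together with a `TraitSchema`
whose position order (eight categorical traits, then growth rate, then
aerial height) fixes the meaning of every ten-element weight vector.
Row order is stable and all tie-breaking downstream refers to it, so a
run is reproducible from the input file alone.

## Dissimilarity

The pipeline's central quantity is weighted Gower dissimilarity

$$d(i,j) = \frac{\sum_t w_t\,\delta_t(i,j)}{\sum_t w_t},\qquad
\delta_t = \begin{cases}
 |x_{it}-x_{jt}|/\mathrm{range}_t & \text{continuous}\\
 \mathbf 1\{x_{it}\neq x_{jt}\}   & \text{categorical,}
\end{cases}$$

with the range taken over the analyzed (complete) table rather than
from theoretical bounds, so the matrix is reproducible from the data
alone. Categorical labels are compared as nominal values even where
they look ordered; converting them to ranks would impose an arbitrary
metric, which is precisely what the mixed-data route avoids. A
continuous trait with zero range carries no information and contributes
0, with a warning. Entries therefore lie in $[0,1]$, and rescaling all
weights by a constant leaves the matrix unchanged.

Seven weight presets (`NoWeight`, `W1`…`W6`) are bundled; they range
from equal weighting to six-fold emphasis of the two continuous traits
(`W6`). For the numeric-conversion pipeline (`toOrdinal()` feeding
`pearsonDistanceMatrix()` or K-means), only the four abundance traits
are convertible (0, 0.25, 0.5, 0.75, 1.0, 1.5 from Not Formed to
Increased); morphology traits have no defensible severity order and are
excluded. The two continuous traits are z-scored there so mm-scale
values are commensurable with the 0--1.5 ordinal scale; this choice is
ours (the conversion route does not prescribe one), and it does not
affect the Gower/PAM route, which uses raw values.

## Clustering

`pamCluster()` is a deterministic Partitioning Around Medoids in the
classic two-phase form: BUILD seeds the medoids greedily (first the
point minimizing total dissimilarity, then whichever point maximizes
the cost reduction), SWAP repeatedly evaluates all (medoid, non-medoid)
exchanges and applies the single best improving one until none
improves. All ties break to the smallest index in table order, so
results are identical across platforms. The objective
$\sum_i d(i,\mathrm{medoid}(i))$ is exposed separately as
`totalCost()`, which also serves the brute-force verification in the
test suite. Two caveats worth knowing: BUILD + SWAP is a greedy
heuristic, and on small unstructured (e.g. uniformly random) instances
it can terminate in a local optimum a percent or two above the
enumeration optimum — the reference implementation in the `cluster`
package lands on the same local optima; and with duplicated records a
medoid may be at distance zero from another cluster's medoid, so
medoids are pinned to their own clusters when labeling.

`agglomerativeCluster()` delegates to `stats::hclust` — Ward in the
ward.D2 convention (squared dissimilarities), or complete linkage — and
cuts at *k*. Applying Ward to a non-Euclidean Gower matrix is a
convention, not a theorem; it is retained because it is the standard
practice for this kind of data. `kmeansCluster()` wraps
`stats::kmeans` (Lloyd) under seeded k-means++ initial centers with a
best-of-restarts rule. k-means++ matters here: with uniform seeding the
chance that one draw of $k$ centers covers $k$ equal planted groups
decays like $k!/k^k$ (under 1% at $k=7$), and the per-$k$ fits inside
the diagnostics would intermittently merge two true clusters. A
degenerate initialization (duplicate centers, an emptied cluster) is
handled by redrawing the centers from the same seeded stream, so the
partition is a pure function of `(x, k, seed, restarts)`.

## Cluster quality and model selection

Two bespoke statistics summarize a clustering. For a continuous trait,
the per-cluster *relative standard deviation* is $100\,\mathrm{SD}/\mu$
(sample SD, $n-1$ denominator — the convention of the toolchain this
mirrors; a singleton reports 0, and a mean below $10^{-9}$ is treated
as undefined rather than divided by). For a categorical trait, the
*percent consensus* is the share of the modal label, ties broken by
vocabulary order and flagged. Run-level per-trait values average the
clusters *unweighted by size* — a 5-gene cluster counts as much as a
171-gene one, which is deliberate: the statistic judges cluster
coherence, not gene coverage. The two composites are the means of the
two continuous and the eight categorical per-trait averages. One
published summary column ("average RSD overall") could not be
reproduced from its stated definition, so the package reports the
documented composite and emits all per-trait columns alongside for
comparison.

`guidelineCheck()` encodes the four published selection guidelines
(cluster floor 3 genes, at most 40 clusters, composite RSD < 15 %,
composite consensus ≥ 95 %), and `weightScan()` tabulates quality over
a presets × k grid, flagging the lexicographic best (max consensus,
then min RSD) while leaving the final choice to the user — the
published selection itself sits just below the consensus guideline, so
verdicts are reported, not enforced. `clusterSummary()` reproduces the
majority-phenotype table: continuous traits are first binned
(`binContinuous()`), and a trait whose top share does not exceed 50 %
prints "Varied".

Binning follows the printed boundaries at their stated one-decimal
precision, each range inclusive. The printed aerial-height ranges leave
a real gap (29.1--29.9 mm between Slightly Reduced and the normal
range); values there are assigned to the neighboring bin above, making
the binning total on $[0,\infty)$. "Increased" counts as a defect in
the global classification (`classifyGlobalPhenotypes()`), which
otherwise flags growth (growth bin outside the three normal bins),
asexual (aerial bin abnormal or either conidial trait non-Normal) and
sexual (any of the six sexual traits non-Normal) defects; whether
faster-than-normal growth belongs among the growth defects is a
convention, chosen here because classification treats every non-normal
bin as a phenotype.

## Expression profiles

`standardizeRows()` rescales each gene's time course to mean 0 and
sample SD 2 (within $10^{-9}$), giving comparable relative expression;
constant rows have no shape and are dropped with a warning rather than
zero-filled, which would drag K-means centroids toward the origin.
`kmeansProfiles()` clusters the standardized curves;
`kDiagnostics()` reports, per candidate $k$: within-cluster sum of
squares, the gap statistic against $B = 50$ uniform reference datasets
sampled within the observed per-time-point ranges (the simplest
reference scheme; gap $=\overline{\log W^\ast}-\log W$ with
$\mathrm{SE}=\mathrm{sd}(\log W^\ast)\sqrt{1+1/B}$, recommendation:
smallest $k$ with $\mathrm{gap}(k)\ge\mathrm{gap}(k+1)-\mathrm{SE}(k+1)$),
and the Davies–Bouldin index
($\overline{\max_{j\ne i}(S_i+S_j)/M_{ij}}$, recommendation: argmin).
The within-SS elbow is left to the eye. The number of profiles is an
input everywhere else: choosing among the three diagnostics is a
judgment call the package does not automate.

`mapProfiles()` intersects the expression and phenotype gene universes,
excludes phenotypic clusters with fewer than 3 expression-covered genes
(too few to call a trend), and calls a profile *dominant* when it
covers at least 40 % of a cluster's covered genes — the threshold is
inclusive, so exactly 40 % qualifies. The run-level summary reports the
mean number of profiles per analyzed cluster and, among clusters with a
dominant profile, the share held by the most common dominant profile.

## Annotation composition and the chromosome test

`composition()` uses the cluster size as denominator, counting genes
missing from the annotation table as FALSE (with a warning): attribute
prevalence is a statement about the cluster, not about the annotated
subset. `chromosomeGof()` is the Pearson goodness-of-fit statistic with
expected counts proportional to the genome's linkage-group totals,
df = 6, upper-tail p; its null is validated in the tests against both
`stats::chisq.test` and a multinomial Monte-Carlo simulation. All
annotation inputs are user-supplied flat files — nothing queries a
service, so runs are reproducible offline.

## Synthetic cohorts

The generators exist so every stage can be exercised against known
truth. `simulatePhenotypes()` draws, per planted cluster, continuous
values from a normal with cluster-specific mean and SD (clipped at 0 —
growth and height are physical) and categorical values equal to the
cluster's modal label with probability $p$ (else uniform over the rest
of the vocabulary). Default archetypes place clusters on a growth ×
aerial grid spanning 20--90 mm/day and 5--50 mm and cycle modal labels
through each vocabulary, so both trait kinds carry signal; the bundled
`publishedCohortConfig()` uses 1168 genes in 40 clusters with the published
size spectrum (5--171, median 14), $p=0.95$ and SD equal to 5 % of the
cluster mean. `simulateExpression()` adds i.i.d. normal noise to
profile templates; the default template list (rise, fall, mid-peak,
cosine, sine, mid-valley, late peak, early peak, each scaled to the
SD-2 standardized scale) is ordered so that every prefix is mutually
well separated — pairwise correlations stay below 0.9 for 4 or more
time points, and the minimum pairwise distance of a 7-template prefix
is ≈ 3 on the SD-2 scale. That separation is a design requirement, not
cosmetics: if two planted templates nearly coincide, the planted $k$
is not identifiable and the Davies–Bouldin argmin legitimately prefers
merging them. `simulateAnnotations()` draws boolean attributes
Bernoulli-conditioned on cluster (forcing GPCR ⊆ transmembrane) and
linkage groups from configurable genome proportions. All generators
are pure functions of their config and seed.

What the synthetic cohorts do **not** emulate: correlated trait noise
(a sick mutant tends to be sick across traits), missing-not-at-random
scoring, batch effects between phenotyping cohorts, and expression
noise that is heteroskedastic in intensity. Passing the recovery tests
therefore shows the pipeline recovers the structure it models, not that
real cohorts are this benign.

## Numerical choices and limitations

* PAM swaps stop when no exchange improves the cost by more than
  $10^{-12}$; costs are non-increasing across iterations and the loop is
  finite.
* Typical problem sizes: the bundled end-to-end runs use the 1168 × 40
  cohort (a weighted-Gower matrix plus a full PAM fit complete in a few
  seconds), 280-gene × 8-time-point expression sets with $B$ = 20--50
  gap references, and $10^5$-draw Monte-Carlo nulls for the chi-square
  validation.
* `runQuality()` requires positive cluster means for the continuous
  traits; a cohort engineered with near-zero growth everywhere would
  need a different spread statistic.
* The weight presets and guidelines are conventions of the study design
  this package operationalizes; nothing in the code assumes they are
  optimal for other organisms or trait panels.
* Reproducing the published run metrics on the real cohort requires the
  study's supplementary per-mutant table, which is not redistributable
  here; with it, the workflow is `readPhenotypeTable()` →
  `filterComplete()` → `gowerMatrix(, "W6")` → `pamCluster(, 40)` →
  `runQuality()`. Cross-implementation PAM tie-breaking can shift
  single genes between clusters, so agreement within about one unit on
  the composite percentages is the realistic expectation.
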