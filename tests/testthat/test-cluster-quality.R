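# Relative SD, percent consensus, run-level quality, guidelines, the
# weight-by-k scan and majority-phenotype summaries.

test_that("relativeSD matches hand computation and conventions", {
  expect_equal(relativeSD(c(80, 80, 80)), 0)
  # sd(c(10,20)) = 7.0711, mean 15 -> 47.14%
  expect_equal(relativeSD(c(10, 20)), 100 * sqrt(50) / 15, tolerance = 1e-12)
  expect_equal(round(relativeSD(c(10, 20)), 2), 47.14)
  expect_equal(relativeSD(42), 0)
  expect_error(relativeSD(c(0, 0)), "mean is not positive")
  expect_error(relativeSD(numeric(0)), "non-empty")
})

test_that("percentConsensus reports the modal share with vocabulary tie-breaks", {
  r <- percentConsensus(c(rep("Reduced", 6), rep("Normal", 4)))
  expect_equal(r$percent, 60)
  expect_equal(r$majority, "Reduced")
  expect_false(r$tie)

  expect_equal(percentConsensus(rep("Normal", 5))$percent, 100)

  r2 <- percentConsensus(c("A", "A", "B", "B"), vocabulary = c("A", "B"))
  expect_equal(r2$percent, 50)
  expect_equal(r2$majority, "A")
  expect_true(r2$tie)
  r3 <- percentConsensus(c("A", "A", "B", "B"), vocabulary = c("B", "A"))
  expect_equal(r3$majority, "B")
  expect_error(percentConsensus(character(0)), "non-empty")
})

test_that("runQuality is exact on pure planted clusters and single clusters", {
  pure <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 3, sizes = c(5, 6, 7), consensus = 1,
    continuousSds = matrix(0, 3, 2), seed = 4))
  asg <- manualAssignment(geneIds(pure$table),
                          pure$labels[geneIds(pure$table)])
  q <- runQuality(asg, pure$table)
  expect_true(all(q@perCluster[, grep("^consensus_", names(q@perCluster))] == 100))
  expect_true(all(q@perCluster[, grep("^rsd_", names(q@perCluster))] == 0))
  expect_equal(q@compositeConsensus, 100)
  expect_equal(q@compositeRSD, 0)

  # one cluster holding the whole table equals direct whole-table statistics
  sim <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 2, sizes = c(15, 15), consensus = 0.7, seed = 8))
  tab <- sim$table
  one <- manualAssignment(geneIds(tab), rep(1L, nrow(tab)))
  q1 <- runQuality(one, tab)
  sc <- traitSchema(tab)
  direct.rsd <- mean(c(relativeSD(tab@data$growth_rate),
                       relativeSD(tab@data$aerial_height)))
  direct.cons <- mean(vapply(
    sc@traits$name[sc@traits$kind == "categorical"],
    function(nm) percentConsensus(tab@data[[nm]],
                                  sc@vocabulary[[nm]])$percent,
    numeric(1)))
  expect_equal(q1@compositeRSD, direct.rsd, tolerance = 1e-12)
  expect_equal(q1@compositeConsensus, direct.cons, tolerance = 1e-12)

  # composites recompute from the per-trait averages
  expect_equal(q1@compositeConsensus,
               mean(q1@perTrait$average[q1@perTrait$kind == "categorical"]))
  expect_equal(q1@compositeRSD,
               mean(q1@perTrait$average[q1@perTrait$kind == "continuous"]))
  expect_error(runQuality(manualAssignment("ghost", 1L), tab),
               "missing from table")
})

test_that("average consensus tracks the planted mixing rate", {
  p <- 0.9
  sim <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 6, sizes = rep(50, 6), consensus = p, seed = 15))
  asg <- manualAssignment(geneIds(sim$table),
                          sim$labels[geneIds(sim$table)])
  q <- runQuality(asg, sim$table)
  # modal share concentrates near 100 p; binomial error over 6x50x8 draws
  expect_lt(abs(q@compositeConsensus - 100 * p), 3)
})

test_that("quality statistics are invariant to record order", {
  sim <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 3, sizes = c(8, 9, 10), consensus = 0.8, seed = 19))
  asg <- manualAssignment(geneIds(sim$table),
                          sim$labels[geneIds(sim$table)])
  q <- runQuality(asg, sim$table)
  perm <- withr::with_seed(1, sample.int(nrow(sim$table)))
  shuffled <- phenotypeTable(sim$table@data[perm, ],
                             traitSchema(sim$table))
  q2 <- runQuality(asg, shuffled)
  expect_equal(q2@perCluster, q@perCluster)
  expect_equal(q2@compositeConsensus, q@compositeConsensus)
  expect_equal(q2@compositeRSD, q@compositeRSD)
})

test_that("merging two pure clusters with different labels lowers consensus", {
  pure <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 2, sizes = c(6, 6), consensus = 1,
    continuousSds = matrix(0, 2, 2), seed = 6))
  ids <- geneIds(pure$table)
  split <- manualAssignment(ids, pure$labels[ids])
  merged <- manualAssignment(ids, rep(1L, length(ids)))
  expect_lt(runQuality(merged, pure$table)@compositeConsensus,
            runQuality(split, pure$table)@compositeConsensus)
})

test_that("guideline verdicts encode the four published thresholds", {
  sim <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 2, sizes = c(5, 2), consensus = 1,
    continuousSds = matrix(0, 2, 2), seed = 2))
  asg <- manualAssignment(geneIds(sim$table),
                          sim$labels[geneIds(sim$table)])
  q <- runQuality(asg, sim$table)
  v <- guidelineCheck(q)
  expect_false(v$min_size_ok)   # a 2-gene cluster breaks the 3-gene floor
  expect_true(v$max_clusters_ok)
  expect_false(v$pass)

  # fabricate run-level values on the report to exercise the thresholds
  q@compositeRSD <- 10.98
  q@compositeConsensus <- 96.0
  q@perCluster$size <- c(5L, 5L)
  expect_true(guidelineCheck(q)$pass)
  q@compositeConsensus <- 94.19
  expect_false(guidelineCheck(q)$consensus_ok)
  expect_false(guidelineCheck(q, maxK = 1)$max_clusters_ok)
  expect_identical(guidelineCheck(q)$pass,
                   with(guidelineCheck(q),
                        min_size_ok && max_clusters_ok && rsd_ok &&
                          consensus_ok))
})

test_that("weightScan produces one verdict row per preset-k pair", {
  sim <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 4, sizes = rep(12, 4), consensus = 0.8, seed = 27))
  scan <- weightScan(sim$table,
                     presets = weightPreset()[c("NoWeight", "W6")],
                     kValues = c(3, 4))
  expect_equal(nrow(scan), 4)
  expect_equal(scan$weights, rep(c("NoWeight", "W6"), each = 2))
  expect_true(all(is.finite(scan$composite_consensus)))
  expect_true(all(is.finite(scan$composite_rsd)))
  expect_equal(sum(scan$best), 1)

  # single preset, single k agrees with a direct runQuality
  one <- weightScan(sim$table, presets = weightPreset()["W6"], kValues = 4)
  direct <- runQuality(pamCluster(gowerMatrix(sim$table, "W6"), 4),
                       sim$table)
  expect_equal(one$composite_consensus, direct@compositeConsensus)
  expect_equal(one$composite_rsd, direct@compositeRSD)
  expect_error(weightScan(sim$table, list(), 3), "non-empty")
})

test_that("continuous up-weighting sharpens recovery when the signal is continuous", {
  # categorical traits near-uninformative, continuous traits separated
  sim <- simulatePhenotypes(phenotypeSimConfig(
    nClusters = 6, sizes = rep(20, 6), consensus = 0.45,
    continuousSdFrac = 0.04, seed = 33))
  scan <- weightScan(sim$table,
                     presets = weightPreset()[c("NoWeight", "W6")],
                     kValues = 6)
  rsd <- with(scan, stats::setNames(composite_rsd, weights))
  expect_lt(rsd[["W6"]], rsd[["NoWeight"]])
})

test_that("cluster summaries report binned majorities or Varied", {
  # 28 genes, 21 with growth in the Normal Average bin -> "75% Normal Average"
  recs <- c(lapply(1:21, function(i) baseRecord(paste0("a", i),
                                                growth_rate = 80)),
            lapply(1:7, function(i) baseRecord(paste0("b", i),
                                               growth_rate = 50)))
  tab <- do.call(makeTable, recs)
  asg <- manualAssignment(geneIds(tab), rep(1L, 28))
  s <- clusterSummary(asg, tab)
  expect_equal(s$growth_rate, "75% Normal Average")
  expect_equal(s$conidia_number, "100% Normal")

  # shares 40/35/25 -> Varied
  recs2 <- c(lapply(1:8, function(i) baseRecord(paste0("x", i),
                                                conidia_number = "Normal")),
             lapply(1:7, function(i) baseRecord(paste0("y", i),
                                                conidia_number = "Reduced")),
             lapply(1:5, function(i) baseRecord(paste0("z", i),
                                                conidia_number = "Not Formed")))
  tab2 <- do.call(makeTable, recs2)
  s2 <- clusterSummary(manualAssignment(geneIds(tab2), rep(1L, 20)), tab2)
  expect_equal(s2$conidia_number, "Varied")

  # a pure cluster is 100% everywhere
  pure <- do.call(makeTable, lapply(1:5, function(i) baseRecord(paste0("p", i))))
  s3 <- clusterSummary(manualAssignment(geneIds(pure), rep(1L, 5)), pure)
  trait.cols <- setdiff(names(s3), c("cluster", "size"))
  expect_true(all(startsWith(unlist(s3[trait.cols]), "100% ")))
})
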