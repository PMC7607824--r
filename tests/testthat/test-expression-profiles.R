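# Row standardization, K-means profiles, k diagnostics and the
# dominant-profile map.

test_that("standardizeRows hits mean 0 / SD 2 and handles degenerate rows", {
  e <- expressionTimeCourse(rbind(g1 = c(1, 2, 3)))
  expect_equal(unname(as.matrix(standardizeRows(e))[1, ]), c(-2, 0, 2))

  std <- standardizeRows(expressionTimeCourse(
    withr::with_seed(1, matrix(rnorm(50 * 6, 5, 3), 50,
                               dimnames = list(paste0("g", 1:50), NULL)))))
  m <- as.matrix(std)
  expect_lt(max(abs(rowMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 1, sd) - 2)), 1e-9)

  # idempotent
  again <- standardizeRows(std)
  expect_equal(as.matrix(again), m, tolerance = 1e-12)

  expect_warning(
    dropped <- standardizeRows(expressionTimeCourse(
      rbind(flat = c(5, 5, 5, 5), ok = c(1, 2, 3, 4)))),
    "constant row")
  expect_equal(geneIds(dropped), "ok")
  expect_error(standardizeRows(expressionTimeCourse(rbind(g = 1))),
               ">= 2 time points")
})

test_that("kmeansProfiles recovers planted profiles and is deterministic", {
  sim <- simulateExpression(expressionSimConfig(
    nProfiles = 3, nTimePoints = 8, genesPerProfile = 30,
    noiseSd = 0, seed = 5))
  std <- standardizeRows(sim$expr)
  fit <- kmeansProfiles(std, 3, seed = 1)
  expect_equal(ari(fit@labels, sim$labels[geneIds(std)]), 1)
  expect_equal(dim(fit@centers), c(3L, 8L))

  fit2 <- kmeansProfiles(std, 3, seed = 1)
  expect_identical(fit@labels, fit2@labels)

  # with all rows distinct, k = gene count gives singleton profiles
  noisy <- simulateExpression(expressionSimConfig(
    nProfiles = 2, nTimePoints = 6, genesPerProfile = 5,
    noiseSd = 0.3, seed = 12))
  nstd <- standardizeRows(noisy$expr)
  singl <- kmeansProfiles(nstd, 10, seed = 1, restarts = 1)
  expect_equal(singl@totalCost, 0, tolerance = 1e-9)
  expect_equal(sort(unique(unname(singl@labels))), 1:10)

  expect_error(kmeansProfiles(sim$expr, 3, seed = 1), "standardized")
})

test_that("k diagnostics: monotone within-SS, DB minimum at planted k, gap mechanics", {
  sim <- simulateExpression(expressionSimConfig(
    nProfiles = 4, nTimePoints = 8, genesPerProfile = 40,
    noiseSd = 0.2, seed = 9))
  std <- standardizeRows(sim$expr)
  diag <- kDiagnostics(std, kRange = 2:8, B = 10, seed = 3)
  expect_true(all(diff(diag$table$withinSS) <= 1e-9))
  expect_equal(diag$dbK, 4)

  # observed within-SS depends only on the data fit, not the references
  d1 <- kDiagnostics(std, kRange = 3:4, B = 1, seed = 3)
  d50 <- kDiagnostics(std, kRange = 3:4, B = 20, seed = 3)
  expect_equal(d1$table$withinSS, d50$table$withinSS, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(d1$table$gap, d50$table$gap)))

  expect_error(kDiagnostics(std, kRange = c(1, 3), B = 2, seed = 1),
               "kRange")
})

test_that("mapProfiles applies the 40% dominance rule and the 3-gene floor", {
  pheno <- manualAssignment(paste0("g", 1:22),
                            rep(1:3, c(10, 10, 2)))
  # cluster 1: 4 genes in profile 1, spread otherwise -> dominant at 40%
  # cluster 2: max share 3/10 -> no dominant profile
  # cluster 3: only 2 genes with expression -> excluded
  prof.labels <- c(1, 1, 1, 1, 2, 2, 3, 3, 4, 4,
                   1, 1, 1, 2, 2, 2, 3, 3, 4, 4,
                   1, 2)
  prof <- manualAssignment(paste0("g", 1:22), prof.labels)
  map <- mapProfiles(pheno, prof)
  pc <- map@perCluster
  expect_equal(pc$cluster, c(1, 2))
  expect_equal(pc$dominantProfile[pc$cluster == 1], 1L)
  expect_equal(pc$dominantShare[pc$cluster == 1], 0.4)
  expect_true(is.na(pc$dominantProfile[pc$cluster == 2]))
  expect_equal(map@excluded$cluster, 3)
  expect_equal(map@excluded$nGenes, 2)
  expect_equal(map@summary$nWithDominant, 1)
  expect_equal(sum(map@crossTab), 22)

  # profiles-per-cluster bound
  expect_true(all(pc$nProfiles >= 1 & pc$nProfiles <= pmin(4, pc$nGenes)))

  expect_error(mapProfiles(pheno, manualAssignment("zz", 1L)),
               "empty intersection")
})

test_that("mapProfiles is invariant to profile relabeling", {
  withr::with_seed(21, {
    pheno <- manualAssignment(paste0("g", 1:60),
                              sample(rep(1:5, c(20, 15, 10, 10, 5))))
    pl <- sample.int(4, 60, replace = TRUE)
  })
  prof <- manualAssignment(paste0("g", 1:60), pl)
  perm <- c(3L, 1L, 4L, 2L)
  prof.perm <- manualAssignment(paste0("g", 1:60), perm[pl])
  m1 <- mapProfiles(pheno, prof)
  m2 <- mapProfiles(pheno, prof.perm)
  expect_equal(m2@perCluster$nProfiles, m1@perCluster$nProfiles)
  expect_equal(m2@perCluster$dominantShare, m1@perCluster$dominantShare)
  expect_equal(m2@summary$avgProfilesPerCluster,
               m1@summary$avgProfilesPerCluster)
  expect_equal(m2@summary$nWithDominant, m1@summary$nWithDominant)
  has1 <- !is.na(m1@perCluster$dominantProfile)
  expect_equal(m2@perCluster$dominantProfile[has1],
               perm[m1@perCluster$dominantProfile[has1]])
})

test_that("expression matrices round-trip through CSV", {
  sim <- simulateExpression(expressionSimConfig(
    nProfiles = 2, nTimePoints = 5, genesPerProfile = 4,
    noiseSd = 0.1, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  m <- as.matrix(sim$expr)
  utils::write.csv(data.frame(gene_id = rownames(m), m,
                              check.names = FALSE), f, row.names = FALSE)
  back <- readExpressionMatrix(f)
  expect_equal(as.matrix(back), m, tolerance = 1e-12)
})
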