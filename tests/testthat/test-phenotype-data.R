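# Phenotype table model: I/O, completeness, binning, ordinal conversion,
# global classification.

test_that("write/read round-trips a valid table and flags missing cells", {
  tab <- makeTable(baseRecord("NCU00001"),
                   baseRecord("NCU00002", growth_rate = 42.5,
                              conidia_number = "Reduced"),
                   baseRecord("NCU00003", aerial_height = 12.1))
  f <- withr::local_tempfile(fileext = ".csv")
  writePhenotypeTable(tab, f)
  back <- readPhenotypeTable(f)
  expect_equal(back@data, tab@data)
  expect_true(all(isComplete(back)))

  tab2 <- makeTable(baseRecord("NCU00001"),
                    baseRecord("NCU00002", ascospore_number = NA))
  writePhenotypeTable(tab2, f)
  back2 <- readPhenotypeTable(f)
  expect_equal(isComplete(back2), c(TRUE, FALSE))
  expect_true(is.na(back2@data$ascospore_number[2]))
})

test_that("reader rejects bad labels, missing columns and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- makeTable(baseRecord("NCU00001"), baseRecord("NCU00002"))
  d <- tab@data
  d$conidia_number[2] <- "Norml"
  utils::write.csv(d, f, row.names = FALSE)
  err <- expect_error(readPhenotypeTable(f), "Norml")
  expect_match(conditionMessage(err), "NCU00002")
  expect_match(conditionMessage(err), "conidia_number")

  utils::write.csv(tab@data[, -2], f, row.names = FALSE)
  expect_error(readPhenotypeTable(f), "schema error")

  d2 <- tab@data
  d2$gene_id <- "NCU00001"
  utils::write.csv(d2, f, row.names = FALSE)
  expect_error(readPhenotypeTable(f), "duplicate gene_id: NCU00001")

  d3 <- tab@data
  d3$growth_rate <- c("80", "fast")
  utils::write.csv(d3, f, row.names = FALSE)
  expect_error(readPhenotypeTable(f), "unparseable")
})

test_that("filterComplete keeps complete records in order", {
  cfg <- phenotypeSimConfig(nClusters = 4, sizes = c(400, 400, 300, 186),
                            nIncomplete = 118L, seed = 11)
  sim <- simulatePhenotypes(cfg)
  # independent counting oracle on the raw data
  n.complete <- sum(stats::complete.cases(
    sim$table@data[, traitSchema(sim$table)@traits$name]))
  expect_equal(n.complete, 1286 - 118)
  kept <- suppressMessages(filterComplete(sim$table))
  expect_equal(nrow(kept), 1168)
  expect_equal(geneIds(kept),
               geneIds(sim$table)[isComplete(sim$table)])

  all.ok <- makeTable(baseRecord("a"), baseRecord("b"))
  expect_equal(suppressMessages(filterComplete(all.ok))@data, all.ok@data)

  none <- makeTable(baseRecord("a", growth_rate = NA),
                    baseRecord("b", conidia_number = NA))
  expect_warning(
    expect_equal(nrow(suppressMessages(filterComplete(none))), 0),
    "no complete records")
})

test_that("continuous binning follows the published boundaries", {
  expect_equal(binContinuous(80, "growth"), "Normal Average")
  expect_equal(binContinuous(39, "growth"), "Severely Reduced")
  expect_equal(binContinuous(46, "aerial"), "Increased")
  # boundary behavior at 1-decimal precision
  expect_equal(binContinuous(c(75, 77.5, 77.6, 82.5, 82.6, 85, 85.1), "growth"),
               c("Normal Low", "Normal Low", "Normal Average",
                 "Normal Average", "Normal High", "Normal High", "Increased"))
  expect_equal(binContinuous(c(39.9, 40, 64.9, 65, 74.9), "growth"),
               c("Severely Reduced", "Reduced", "Reduced",
                 "Slightly Reduced", "Slightly Reduced"))
  expect_equal(binContinuous(c(14.9, 15, 24.9, 25, 29, 30, 35, 35.1,
                               39.9, 40, 45), "aerial"),
               c("Severely Reduced", "Reduced", "Reduced",
                 "Slightly Reduced", "Slightly Reduced", "Normal Low",
                 "Normal Low", "Normal Average", "Normal Average",
                 "Normal High", "Normal High"))
  # the printed 29-30 mm gap is closed upward
  expect_equal(binContinuous(29.5, "aerial"), "Normal Low")
  expect_error(binContinuous(-1, "growth"), "domain error")
})

test_that("binning is total on [0, Inf)", {
  withr::with_seed(5, {
    v <- c(runif(500, 0, 200), seq(0, 100, by = 0.1))
    expect_false(anyNA(binContinuous(v, "growth")))
    expect_false(anyNA(binContinuous(v, "aerial")))
  })
})

test_that("ordinal conversion maps severities and z-scores continuous traits", {
  m <- defaultOrdinalMapping()
  expect_equal(unname(m[c("Not Formed", "Normal", "Increased")]),
               c(0, 1.0, 1.5))
  tab <- makeTable(baseRecord("a", conidia_number = "Not Formed",
                              aerial_height = 30),
                   baseRecord("b", growth_rate = 60),
                   baseRecord("c", conidia_number = "Increased",
                              growth_rate = 100, aerial_height = 44))
  x <- toOrdinal(tab)
  expect_equal(dim(x), c(3L, 6L))
  expect_equal(unname(x[, "conidia_number"]), c(0, 1.0, 1.5))
  expect_equal(unname(x["b", 3:6]), c(1, 1, 1, 1))
  expect_equal(mean(x[, "growth_rate"]), 0)
  expect_equal(stats::sd(x[, "growth_rate"]), 1)
  # a label the mapping does not cover aborts with trait and label
  short <- m[names(m) != "Increased"]
  expect_error(toOrdinal(tab, short), "conidia_number.*Increased")
})

test_that("global phenotype classification counts planted defects", {
  normals <- lapply(1:3, function(i) baseRecord(paste0("wt", i)))
  growth.only <- lapply(1:7, function(i)
    baseRecord(paste0("gr", i), growth_rate = 50))
  asex.only <- lapply(1:2, function(i)
    baseRecord(paste0("as", i), conidia_number = "Reduced"))
  both <- list(baseRecord("gs1", growth_rate = 50,
                          perithecia_number = "Reduced"))
  tab <- do.call(makeTable, c(normals, growth.only, asex.only, both))
  g <- classifyGlobalPhenotypes(tab)
  expect_equal(unname(g$counts), c(8, 2, 1))
  expect_equal(g$totalGlobalPhenotypes, 11)
  expect_equal(g$nWithPhenotype, 10)
  expect_equal(g$nNoPhenotype, 3)
  expect_equal(sum(g$venn), g$nWithPhenotype)
  # any_defect iff at least one class flag
  expect_equal(g$flags$any_defect,
               g$flags$growth_defect | g$flags$asexual_defect |
                 g$flags$sexual_defect)
  # class-count sandwich
  expect_true(g$nWithPhenotype <= sum(g$counts))
  expect_true(sum(g$counts) <= 3 * g$nWithPhenotype)

  # increased growth counts as a growth defect, nothing else
  g2 <- classifyGlobalPhenotypes(makeTable(baseRecord("x", growth_rate = 90)))
  expect_equal(unname(g2$counts), c(1, 0, 0))

  expect_error(
    classifyGlobalPhenotypes(makeTable(baseRecord("x",
                                                  growth_rate = NA_real_))),
    "precondition")
})
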