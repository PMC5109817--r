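test_that("evaluating the entire collection against itself gives the identity values", {
  col <- simpleCollection(nQuant = 3, nQual = 2, n = 12, seed = 101)
  res <- evaluateContinuous(accessionIds(col), col)
  expect_equal(res$MD, 0)
  expect_equal(res$VD, 0)
  expect_equal(res$CR, 100)
  expect_equal(res$VR, 100)
  cat_ <- evaluateCategorical(accessionIds(col), col)
  expect_equal(cat_$core$I, cat_$entire$I)
  expect_equal(cat_$core$J, cat_$entire$J)
  rep <- evaluateCore(accessionIds(col), col)
  expect_true(rep@verdict)
})

test_that("range coincidence is the plain range ratio", {
  g <- randomGenotypeMatrix(4, 2, missingRate = 0)
  vals <- data.frame(tr = c(0, 10, 5, 2), row.names = accessionIds(g))
  ph <- PhenotypeTable(vals, data.frame(name = "tr", kind = "quantitative"))
  col <- mergeCollection(g, ph)
  core <- accessionIds(g)[c(1, 3)]       # values {0, 5}: half the range
  res <- evaluateContinuous(core, col)
  expect_equal(res$CR, 50)
})

test_that("aggregates match a hand-computed two-trait spreadsheet", {
  g <- randomGenotypeMatrix(5, 2, missingRate = 0)
  ids <- accessionIds(g)
  vals <- data.frame(t1 = c(10, 12, 14, 16, 18),
                     t2 = c(2, 4, 9, 5, 10), row.names = ids)
  ph <- PhenotypeTable(vals, data.frame(name = c("t1", "t2"),
                                        kind = "quantitative"))
  col <- mergeCollection(g, ph)
  core <- ids[c(1, 3, 5)]                # t1: {10,14,18}, t2: {2,9,10}
  res <- evaluateContinuous(core, col)
  # hand computation (means, n-1 variances, ranges, CVs)
  md <- 100 * mean(c(abs(14 - 14) / 14, abs(6 - 7) / 6))
  vd <- 100 * mean(c(abs(10 - 16) / 10, abs(11.5 - 19) / 11.5))
  cr <- 100 * mean(c(8 / 8, 8 / 8))
  cvE <- c(sqrt(10) / 14, sqrt(11.5) / 6)
  cvC <- c(4 / 14, sqrt(19) / 7)
  vr <- 100 * mean(cvC / cvE)
  expect_equal(res$MD, md, tolerance = 1e-12)
  expect_equal(res$VD, vd, tolerance = 1e-12)
  expect_equal(res$CR, cr, tolerance = 1e-12)
  expect_equal(res$VR, vr, tolerance = 1e-12)
})

test_that("MD/VD are invariant to positive rescaling; CR/VR to positive affine maps", {
  col <- simpleCollection(nQuant = 2, nQual = 1, n = 10, seed = 103)
  core <- accessionIds(col)[c(1, 4, 7, 9)]
  base <- evaluateContinuous(core, col)
  scaled <- col
  scaled@phenotypes@values$qt1 <- 3.7 * scaled@phenotypes@values$qt1
  scaled@phenotypes@values$qt2 <- 0.2 * scaled@phenotypes@values$qt2
  res <- evaluateContinuous(core, scaled)
  expect_equal(res$MD, base$MD, tolerance = 1e-12)
  expect_equal(res$VD, base$VD, tolerance = 1e-12)
  expect_equal(res$CR, base$CR, tolerance = 1e-12)
  expect_equal(res$VR, base$VR, tolerance = 1e-12)
  shifted <- col
  shifted@phenotypes@values$qt1 <- 2 * shifted@phenotypes@values$qt1 + 50
  res2 <- evaluateContinuous(core, shifted)
  expect_equal(res2$CR, base$CR, tolerance = 1e-12)   # scale cancels in ranges
  expect_false(isTRUE(all.equal(res2$MD, base$MD)))   # MD is origin-sensitive
})

test_that("the count form reports percentages of significant differences", {
  col <- simpleCollection(nQuant = 3, nQual = 1, n = 30, seed = 107)
  res <- evaluateContinuous(accessionIds(col)[1:10], col, form = "count")
  expect_true(res$MD >= 0 && res$MD <= 100)
  expect_true(res$MD %in% (100 * (0:3) / 3))
})

test_that("a skewed entire collection can be out-evened by a small core", {
  calls <- rbind(matrix("A/A", 8, 1), matrix("B/B", 2, 1))
  rownames(calls) <- sprintf("s%02d", 1:10); colnames(calls) <- "m1"
  col <- mergeCollection(GenotypeMatrix(calls))
  cat_ <- evaluateCategorical(c("s01", "s09"), col)   # one of each pattern
  expect_gt(cat_$core$I, cat_$entire$I)
  expect_true(all(cat_$perVariable$JEntire >= 0 & cat_$perVariable$JEntire <= 1))
  expect_true(all(cat_$perVariable$JCore >= 0 & cat_$perVariable$JCore <= 1))
})

test_that("fixed and per-column I_max conventions differ as documented", {
  calls <- rbind(matrix("A/A", 6, 1), matrix("A/B", 3, 1), matrix("B/B", 1, 1))
  rownames(calls) <- sprintf("s%02d", 1:10); colnames(calls) <- "m1"
  col <- mergeCollection(GenotypeMatrix(calls))
  core <- c("s01", "s07")                 # two of the three patterns
  fixed <- evaluateCategorical(core, col, convention = "fixed")
  perCol <- evaluateCategorical(core, col, convention = "per-column")
  expect_equal(fixed$perVariable$IMaxCore, log(3))
  expect_equal(perCol$perVariable$IMaxCore, log(2))
  expect_gt(perCol$core$J, fixed$core$J)
})

test_that("hold-out validation refuses overlapping markers and reports per-column I_max", {
  sim <- simulateCollection(simulationConfig(100, nMarkers = 8, K = 3,
                                             fDiv = 0.4, nHoldoutMarkers = 2,
                                             missingRate = 0, seed = 31))
  col <- sim$collection
  core <- accessionIds(col)[1:20]
  hv <- validateHoldout(core, col)
  expect_true(all(hv$perMarker$nPatternsCore <= hv$perMarker$nPatternsEntire))
  expect_equal(hv$perMarker$IMaxEntire, log(hv$perMarker$nPatternsEntire))
  expect_equal(hv$perMarker$IMaxCore, log(hv$perMarker$nPatternsCore))
  expect_true(all(hv$perMarker$IEntire <= hv$perMarker$IMaxEntire + 1e-12))
  # a hold-out panel sharing ids with the selection panel is rejected
  expect_error(validateHoldout(core, col, col@genotypes), "overlap")
  # a core retaining all patterns reports equal counts
  hvAll <- validateHoldout(accessionIds(col), col)
  expect_equal(hvAll$perMarker$nPatternsCore, hvAll$perMarker$nPatternsEntire)
})

test_that("evaluateCore assembles the full report and rejects empty cores", {
  sim <- simulateCollection(simulationConfig(120, nMarkers = 10, K = 2,
                                             fDiv = 0.3, nTraitsQuant = 3,
                                             nTraitsQual = 2,
                                             nHoldoutMarkers = 1,
                                             missingRate = 0, seed = 37))
  col <- sim$collection
  core <- runStrategy(col, "G+Pcc")
  rep <- evaluateCore(core, col)
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(rep@nCore, length(coreIds(core)))
  expect_false(is.null(rep@holdout))
  expect_error(evaluateCore(character(0), col), "empty core")
})

test_that("the strategy comparison table carries one column per core plus the entire collection", {
  sim <- simulateCollection(simulationConfig(100, nMarkers = 10, K = 2,
                                             fDiv = 0.3, nTraitsQuant = 2,
                                             nTraitsQual = 2, missingRate = 0,
                                             seed = 41))
  col <- sim$collection
  cl <- sim$truth@cluster
  cores <- list()
  reports <- list()
  for (s in c("Gcc", "Gg+Pcc")) {
    cores[[s]] <- runStrategy(col, s, clusters = cl)
    reports[[s]] <- evaluateCore(cores[[s]], col)
  }
  cmp <- strategyComparison(reports, cores)
  expect_equal(names(cmp), c("parameter", "Gcc", "Gg+Pcc", "entire"))
  expect_equal(cmp$entire[cmp$parameter == "entries"], 100)
  nAlleleClasses <- ncol(buildClassification(col, "genotype")@membership)
  expect_equal(cmp$Gcc[cmp$parameter == "classes"], nAlleleClasses)
})
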