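test_that("Sturges binning matches the rule and its boundary contract", {
  set.seed(11)
  e236 <- sturgesBins(runif(236))
  expect_equal(attr(e236, "k"), 9L)        # ceil(1 + log2 236)
  e64 <- sturgesBins(runif(64))
  expect_equal(attr(e64, "k"), 7L)         # 1 + 6 exact
  v <- 0:9
  edges <- sturgesBins(v)
  k <- attr(edges, "k")
  expect_equal(diff(edges), rep(9 / k, k), tolerance = 1e-12)
  bins <- germCore:::.binAssign(v, edges)
  expect_equal(bins[1], 1L)                # min in the bottom bin
  expect_equal(bins[length(v)], k)         # max in the top bin
  # a value sitting exactly on an internal edge joins the lower bin
  expect_equal(germCore:::.binAssign(edges[2], edges), 1L)
  expect_warning(sturgesBins(c(3, 3, 3)), "constant")
  expect_error(sturgesBins(c(1, NA)), "at least 2")
})

test_that("classification counts alleles, categories and bins as classes", {
  sim <- simulateCollection(simulationConfig(236, nMarkers = 48, K = 3,
                                             missingRate = 0,
                                             nTraitsQuant = 2, nTraitsQual = 2,
                                             seed = 13))
  col <- sim$collection
  ctG <- buildClassification(col, "genotype")
  expect_equal(ncol(ctG@membership), 96)   # 48 biallelic markers, 2 alleles each
  ctP <- buildClassification(col, "phenotype")
  ctB <- buildClassification(col, "both")
  expect_equal(ncol(ctB@membership), ncol(ctG@membership) + ncol(ctP@membership))
  # heterozygote carries both alleles; homozygote carries one
  het <- which(genotypeCalls(col)[, 1] == "A/B")[1]
  expect_equal(sum(ctG@membership[het, 1:2]), 2)
  expect_true(all(colSums(ctB@membership) > 0))
  expect_error(buildClassification(mergeCollection(col@genotypes), "phenotype"),
               "phenotype")
})

test_that("accessions missing a trait value carry no class for it", {
  g <- randomGenotypeMatrix(4, 2, missingRate = 0)
  vals <- data.frame(qt = c(1, 2, 3, NA), ct = c("x", "y", NA, "x"),
                     row.names = accessionIds(g))
  ph <- suppressWarnings(PhenotypeTable(
    vals, data.frame(name = c("qt", "ct"),
                     kind = c("quantitative", "qualitative")),
    list(ct = c("x", "y"))))
  ct <- buildClassification(mergeCollection(g, ph), "phenotype")
  qtCols <- ct@states$variable == "qt"
  ctCols <- ct@states$variable == "ct"
  expect_equal(sum(ct@membership[4, qtCols]), 0)
  expect_equal(sum(ct@membership[3, ctCols]), 0)
})

test_that("greedy selection solves the documented small instance", {
  M <- rbind(a1 = c(TRUE, TRUE, FALSE),
             a2 = c(FALSE, FALSE, TRUE),
             a3 = c(TRUE, FALSE, TRUE),
             a4 = c(FALSE, TRUE, TRUE))
  colnames(M) <- c("a", "b", "c")
  core <- mStrategySelect(asClassificationTable(M))
  expect_equal(length(coreIds(core)), 2L)          # brute-force minimum is 2
  expect_true(all(colSums(M[coreIds(core), ]) > 0))
  # one accession carrying everything: core of size 1
  M1 <- rbind(solo = c(TRUE, TRUE), other = c(TRUE, FALSE))
  colnames(M1) <- c("a", "b")
  expect_equal(coreIds(mStrategySelect(asClassificationTable(M1))), "solo")
})

test_that("greedy cores always cover and stay within +1 of the exhaustive optimum", {
  set.seed(47)
  for (rep in 1:20) {
    M <- randomMembership(sample(5:12, 1), sample(4:10, 1),
                          p = runif(1, 0.15, 0.5))
    core <- mStrategySelect(asClassificationTable(M))
    expect_true(all(colSums(M[coreIds(core), , drop = FALSE]) > 0))
    expect_lte(length(coreIds(core)), oracleMinCoverSize(M) + 1L)
  }
})

test_that("selection is deterministic and independent of accession order", {
  set.seed(59)
  M <- randomMembership(10, 8)
  core1 <- mStrategySelect(asClassificationTable(M))
  perm <- sample(10)
  core2 <- mStrategySelect(asClassificationTable(M[perm, ]))
  expect_setequal(coreIds(core1), coreIds(core2))
  expect_identical(coreIds(core1),
                   coreIds(mStrategySelect(asClassificationTable(M))))
})

test_that("rare-class tie-break prefers carriers of rare classes", {
  # both b1 and b2 gain 2 classes; b2's classes are rarer
  M <- rbind(b1 = c(TRUE, TRUE, FALSE, FALSE),
             b2 = c(FALSE, FALSE, TRUE, TRUE),
             f1 = c(TRUE, FALSE, FALSE, FALSE),
             f2 = c(TRUE, TRUE, FALSE, FALSE))
  colnames(M) <- c("c1", "c2", "c3", "c4")
  core <- mStrategySelect(asClassificationTable(M))
  expect_equal(coreIds(core)[1], "b2")
})

test_that("stratified selection unions per-cluster cores with full coverage", {
  sim <- simulateCollection(simulationConfig(120, nMarkers = 12, K = 3,
                                             fDiv = 0.4, missingRate = 0.01,
                                             nTraitsQuant = 2, nTraitsQual = 2,
                                             seed = 17))
  col <- sim$collection
  cl <- sim$truth@cluster
  strat <- stratifiedSelect(col, cl, basis = "genotype", strategy = "Ggcc")
  expect_equal(strat@classesCovered, strat@classesTotal)
  # every allele/category class observed anywhere is observed in some
  # cluster, hence covered by the union of per-cluster cores
  ctBoth <- buildClassification(col, "both")
  catCols <- ctBoth@states$source != "quant-trait"
  stratBoth <- stratifiedSelect(col, cl, basis = "both", strategy = "Gg+Pcc")
  expect_true(all(colSums(ctBoth@membership[coreIds(stratBoth),
                                            catCols, drop = FALSE]) > 0))
  flat <- mStrategySelect(buildClassification(col, "genotype"),
                          strategy = "Gcc", basis = "genotype")
  expect_gte(length(coreIds(strat)), length(coreIds(flat)))
  # k = 1 stratification degenerates to the unstratified selection
  one <- stratifiedSelect(col, setNames(rep(1L, 120), accessionIds(col)),
                          basis = "genotype")
  expect_setequal(coreIds(one), coreIds(flat))
  # singleton cluster contributes its sole accession, with a warning
  cl2 <- cl
  cl2[1] <- 99L
  expect_warning(s2 <- stratifiedSelect(col, cl2, basis = "genotype"),
                 "singleton")
  expect_true(names(cl2)[1] %in% coreIds(s2))
})

test_that("runStrategy dispatches bases and stratification per strategy tag", {
  sim <- simulateCollection(simulationConfig(100, nMarkers = 10, K = 2,
                                             fDiv = 0.3, missingRate = 0,
                                             nTraitsQuant = 2, nTraitsQual = 2,
                                             seed = 21))
  col <- sim$collection
  cl <- sim$truth@cluster
  gcc <- runStrategy(col, "Gcc")
  expect_equal(gcc@basis, "genotype")
  expect_setequal(coreIds(gcc),
                  coreIds(mStrategySelect(buildClassification(col, "genotype"))))
  pcc <- runStrategy(col, "Pcc")
  expect_equal(pcc@basis, "phenotype")
  both <- runStrategy(col, "G+Pcc")
  expect_equal(both@basis, "both")
  expect_error(runStrategy(col, "Ggcc"), "cluster")
  ggcc <- runStrategy(col, "Ggcc", clusters = cl)
  expect_equal(ggcc@strategy, "Ggcc")
  expect_equal(ggcc@classesCovered, ggcc@classesTotal)
})

test_that("adding variables never shrinks the selected core", {
  sim <- simulateCollection(simulationConfig(80, nMarkers = 8, K = 2,
                                             missingRate = 0,
                                             nTraitsQuant = 2, nTraitsQual = 2,
                                             seed = 25))
  col <- sim$collection
  nG <- length(coreIds(runStrategy(col, "Gcc")))
  nGP <- length(coreIds(runStrategy(col, "G+Pcc")))
  expect_gte(nGP, nG)
})
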