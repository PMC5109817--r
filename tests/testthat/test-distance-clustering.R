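test_that("Manhattan dissimilarity hits the dosage endpoints", {
  calls <- rbind(a = c("A/A", "A/A"), b = c("A/A", "A/A"),
                 c = c("B/B", "B/B"))
  colnames(calls) <- c("m1", "m2")
  D <- manhattanDissimilarity(GenotypeMatrix(calls))
  expect_equal(D$d["a", "b"], 0)
  expect_equal(D$d["a", "c"], 1)    # opposite homozygotes at every marker
  # AA vs AB at 1 of 2 markers, identical at the other: (1/2)/2
  calls2 <- rbind(x = c("A/A", "A/A"), y = c("A/B", "A/A"))
  colnames(calls2) <- c("m1", "m2")
  D2 <- manhattanDissimilarity(GenotypeMatrix(calls2))
  expect_equal(D2$d["x", "y"], 0.25)
})

test_that("dissimilarity uses pairwise deletion and errors on disjoint pairs", {
  calls <- rbind(a = c("A/A", NA, "A/B"), b = c("A/B", "B/B", NA),
                 c = c(NA, "B/B", "A/A"))
  colnames(calls) <- c("m1", "m2", "m3")
  D <- manhattanDissimilarity(GenotypeMatrix(calls))
  expect_equal(unname(D$nShared["a", "b"]), 1)
  expect_equal(D$d["a", "b"], 0.5)  # only m1 shared: AA vs AB is |2-1|/2
  bad <- rbind(a = c("A/A", NA), b = c(NA, "B/B"))
  colnames(bad) <- c("m1", "m2")
  expect_error(manhattanDissimilarity(GenotypeMatrix(bad)), "a.*b|b.*a")
})

test_that("dissimilarities satisfy matrix axioms on random data (incl. multi-allelic)", {
  set.seed(31)
  g <- randomGenotypeMatrix(10, 6, missingRate = 0.1,
                            alleles = c("A", "B", "C", "D"))
  D <- manhattanDissimilarity(g)$d
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(0, 10))
  expect_equal(D, t(D))
  # the triangle inequality holds on complete data (means of per-marker
  # metrics); pairwise deletion can break it, which is why nShared is reported
  g2 <- randomGenotypeMatrix(10, 6, missingRate = 0,
                             alleles = c("A", "B", "C", "D"))
  D2 <- manhattanDissimilarity(g2)$d
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(D2[i, j], D2[i, k] + D2[k, j] + 1e-9)
})

test_that("neighbor joining recovers a known 4-taxon additive tree exactly", {
  # quartet ((t1:1,t2:2):5,(t3:3,t4:4)) => additive distances
  d <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  tree <- njTree(d)
  expect_s3_class(tree, "phylo")
  dd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(dd, d, tolerance = 1e-9)
  # correct split: (t1,t2) | (t3,t4)
  skip_if_not_installed("phangorn")
  truth <- ape::read.tree(text = "((t1:1,t2:2):5,(t3:3,t4:4):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(truth)), 0)
})

test_that("3-taxon NJ yields the closed-form star branch lengths", {
  d <- matrix(c(0, 0.4, 0.6, 0.4, 0, 0.8, 0.6, 0.8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- njTree(d)
  bl <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                        tree$edge[, 2])], tree$tip.label)
  expect_equal(unname(bl["x"]), (0.4 + 0.6 - 0.8) / 2)
  expect_equal(unname(bl["y"]), (0.4 + 0.8 - 0.6) / 2)
  expect_equal(unname(bl["z"]), (0.6 + 0.8 - 0.4) / 2)
})

test_that("NJ recovers random additive trees and is order-invariant", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (nTips in c(6, 8)) {
    gen <- randomAdditiveDistance(nTips)
    tree <- njTree(gen$d)
    expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(gen$tree)), 0)
    expect_equal(ape::cophenetic.phylo(tree)[rownames(gen$d), colnames(gen$d)],
                 gen$d, tolerance = 1e-9)
    perm <- sample(nTips)
    tree2 <- njTree(gen$d[perm, perm])
    expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(tree2)), 0)
  }
})

test_that("NJ picks the least-squares-best topology among all 5-taxon trees", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  gen <- randomAdditiveDistance(5)
  njT <- ape::unroot(njTree(gen$d))
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = rownames(gen$d))
  sse <- vapply(all5, lsTopologyFit, 0, d = gen$d)
  best <- all5[[which.min(sse)]]
  expect_equal(phangorn::RF.dist(njT, ape::unroot(best)), 0)
})

test_that("UPGMA is ultrametric, monotone, and exact on ultrametric input", {
  set.seed(41)
  # random ultrametric distances from a coalescent-style dendrogram
  tr <- ape::rcoal(8)
  tr$tip.label <- sprintf("u%02d", 1:8)
  d <- ape::cophenetic.phylo(tr)
  tree <- upgmaTree(d)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  expect_lt(diff(range(depth)), 1e-9)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  hc <- attr(tree, "hclust")
  expect_true(all(diff(hc$height) >= -1e-12))
  # two taxa at d = 0.4 join at height 0.2
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  t2 <- upgmaTree(d2)
  expect_equal(attr(t2, "hclust")$height, 0.4)
  expect_equal(t2$edge.length, c(0.2, 0.2))
})

test_that("UPGMA is invariant to leaf input order", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  g <- randomGenotypeMatrix(12, 8, missingRate = 0)
  D <- manhattanDissimilarity(g)$d
  t1 <- upgmaTree(D)
  perm <- sample(12)
  t2 <- upgmaTree(D[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
})

test_that("tree cutting yields nested partitions and refuses NJ trees", {
  set.seed(61)
  g <- randomGenotypeMatrix(10, 8, missingRate = 0)
  D <- manhattanDissimilarity(g)
  tree <- upgmaTree(D)
  expect_equal(as.integer(table(cutTree(tree, 1))), 10L)
  expect_equal(length(unique(cutTree(tree, 10))), 10)
  cl3 <- cutTree(tree, 3)
  cl4 <- cutTree(tree, 4)
  # k=4 refines k=3: members of one 4-cluster share their 3-cluster label
  for (k in unique(cl4))
    expect_equal(length(unique(cl3[names(cl4)[cl4 == k]])), 1L)
  expect_error(cutTree(njTree(D), 3), "UPGMA")
  expect_error(cutTree(tree, 0), "k must be")
})

test_that("tree cutting at the true K recovers simulated clusters", {
  skip_if_not_installed("mclust")
  sim <- simulateCollection(simulationConfig(200, nMarkers = 48, K = 5,
                                             fDiv = 0.5, fIs = 0.7,
                                             missingRate = 0.01, seed = 1))
  D <- manhattanDissimilarity(sim$collection@genotypes)
  cl <- cutTree(upgmaTree(D), 5)
  ari <- mclust::adjustedRandIndex(cl[names(sim$truth@cluster)],
                                   sim$truth@cluster)
  expect_gte(ari, 0.9)
})

test_that("PCoA reproduces known configurations", {
  # 3 collinear equidistant points: one positive axis carries everything
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  res <- suppressWarnings(runPcoa(d, nAxes = 2))
  expect_equal(res$pctVariance[1], 100, tolerance = 1e-9)
  # planar points: Euclidean distances recover the configuration up to rigid motion
  skip_if_not_installed("vegan")
  set.seed(71)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  dE <- as.matrix(stats::dist(pts))
  res2 <- runPcoa(dE, nAxes = 2)
  pro <- vegan::procrustes(pts, res2$coordinates, symmetric = FALSE)
  expect_lt(sqrt(mean(stats::residuals(pro)^2)), 1e-9)
  expect_true(all(diff(res2$pctVariance) <= 1e-12))
})

test_that("PCoA of Euclidean dosage distances matches PCA eigenvalues", {
  set.seed(83)
  X <- matrix(rnorm(60), 12, 5)
  d <- as.matrix(stats::dist(X))
  res <- suppressWarnings(runPcoa(d, nAxes = 5))
  pcaEig <- prcomp(X, center = TRUE, scale. = FALSE)$sdev^2 * (12 - 1)
  expect_equal(res$eigenvalues[1:5], pcaEig[1:5], tolerance = 1e-9)
})

test_that("Newick export/import round-trips trees and quoted labels", {
  skip_if_not_installed("phangorn")
  set.seed(97)
  tree <- ape::rtree(6)
  tree$tip.label <- c("plain", "with space", letters[1:4])
  path <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(tree, path)
  back <- importNewick(path)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(phangorn::RF.dist(back, tree), 0)
  for (rep in 1:3) {
    t0 <- ape::rtree(sample(4:10, 1))
    exportNewick(t0, path)
    expect_equal(phangorn::RF.dist(importNewick(path), t0), 0)
  }
})
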