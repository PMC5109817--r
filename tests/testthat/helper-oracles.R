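# Fixtures built in code, and independent brute-force oracles used to check
# the package's closed-form statistics and the greedy core selector.

toyGenotypes <- function() {
  m <- matrix(c("A/A", "A/B", "./.", "B/B"), nrow = 2, byrow = FALSE,
              dimnames = list(c("acc1", "acc2"), c("m1", "m2")))
  GenotypeMatrix(m)
}

randomGenotypeMatrix <- function(n, m, missingRate = 0.1,
                                 alleles = c("A", "B", "C")) {
  calls <- matrix(NA_character_, n, m,
                  dimnames = list(sprintf("a%02d", seq_len(n)),
                                  sprintf("mk%02d", seq_len(m))))
  for (j in seq_len(m)) {
    al <- sample(alleles, sample(2:length(alleles), 1L))
    for (i in seq_len(n)) {
      if (runif(1) < missingRate) next
      calls[i, j] <- paste(sort(sample(al, 2L, replace = TRUE)), collapse = "/")
    }
  }
  # guarantee at least one non-missing call per accession
  for (i in seq_len(n)) if (all(is.na(calls[i, ]))) calls[i, 1L] <- "A/A"
  GenotypeMatrix(calls)
}

# --- enumeration oracles for allele-frequency statistics ------------------

# allele copies at one marker for a set of accessions
.oracleCopies <- function(g, marker, ids) {
  obs <- genotypeCalls(g)[ids, marker]
  obs <- obs[!is.na(obs)]
  unname(unlist(strsplit(obs, "/", fixed = TRUE)))
}

# H_E as the probability that two independent draws (with replacement) from
# the allele-copy pool differ, by exhaustive enumeration of ordered pairs
oracleExpectedHet <- function(g, marker, ids) {
  a <- .oracleCopies(g, marker, ids)
  pairs <- expand.grid(x = a, y = a, stringsAsFactors = FALSE)
  mean(pairs$x != pairs$y)
}

# PIC = 1 - sum p^2 - sum_{i<j} 2 p_i^2 p_j^2, via enumeration of ordered
# 4-tuples of allele copies: sum p^2 = P(two draws equal),
# (sum p^2)^2 = P(draw1==draw2 & draw3==draw4), sum p^4 = P(all four equal)
oraclePic <- function(g, marker, ids) {
  a <- .oracleCopies(g, marker, ids)
  n <- length(a)
  p2 <- 0; p22 <- 0; p4 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    eq12 <- a[i] == a[j]
    p2 <- p2 + eq12
    for (k in seq_len(n)) for (l in seq_len(n)) {
      eq34 <- a[k] == a[l]
      p22 <- p22 + (eq12 && eq34)
      p4 <- p4 + (eq12 && eq34 && a[j] == a[k])
    }
  }
  p2 <- p2 / n^2; p22 <- p22 / n^4; p4 <- p4 / n^4
  1 - p2 - (p22 - p4)
}

oracleObservedHet <- function(g, marker, ids) {
  obs <- genotypeCalls(g)[ids, marker]
  obs <- obs[!is.na(obs)]
  parts <- strsplit(obs, "/", fixed = TRUE)
  mean(vapply(parts, function(p) p[1] != p[2], TRUE))
}

oracleShannonPatterns <- function(g, marker, ids) {
  obs <- genotypeCalls(g)[ids, marker]
  obs <- obs[!is.na(obs)]
  total <- 0
  for (pat in unique(obs)) {
    f <- sum(obs == pat) / length(obs)
    total <- total - f * log(f)
  }
  total
}

# --- exhaustive minimum set cover ----------------------------------------

# smallest number of accessions (rows of a logical membership matrix)
# covering every column, by enumeration over subsets of increasing size
oracleMinCoverSize <- function(M) {
  n <- nrow(M)
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size)
    for (c_ in seq_len(ncol(combs))) {
      if (all(colSums(M[combs[, c_], , drop = FALSE]) > 0)) return(size)
    }
  }
  stop("no cover exists")
}

randomMembership <- function(nAcc, nClass, p = 0.3) {
  repeat {
    M <- matrix(runif(nAcc * nClass) < p, nAcc, nClass,
                dimnames = list(sprintf("a%02d", seq_len(nAcc)),
                                sprintf("c%02d", seq_len(nClass))))
    if (all(colSums(M) > 0) && all(rowSums(M) > 0)) return(M)
  }
}

# wrap a bare membership matrix as a ClassificationTable
asClassificationTable <- function(M) {
  new("ClassificationTable", membership = M,
      states = data.frame(variable = colnames(M), class = colnames(M),
                          source = "marker", stringsAsFactors = FALSE),
      variables = data.frame(name = colnames(M), source = "marker",
                             nClasses = 1L, stringsAsFactors = FALSE),
      binEdges = list())
}

# least-squares branch-length fit of a fixed unrooted topology to a distance
# matrix; returns the SSE (used to brute-force the best topology)
lsTopologyFit <- function(tree, d) {
  tips <- tree$tip.label
  nEdge <- nrow(tree$edge)
  pairs <- utils::combn(length(tips), 2)
  X <- matrix(0, ncol(pairs), nEdge)
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    path <- ape::nodepath(tree, i, j)
    onPath <- apply(tree$edge, 1, function(e)
      any(e[1] == path[-length(path)] & e[2] == path[-1]) ||
      any(e[2] == path[-length(path)] & e[1] == path[-1]))
    X[p, onPath] <- 1
    y[p] <- d[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# a random additive distance matrix from a random unrooted binary tree
randomAdditiveDistance <- function(nTips) {
  tree <- ape::rtree(nTips, rooted = FALSE,
                     br = function(n) runif(n, 0.2, 2))
  tree$tip.label <- sprintf("t%02d", seq_len(nTips))
  d <- ape::cophenetic.phylo(tree)
  list(tree = tree, d = d[order(rownames(d)), order(colnames(d))])
}

simpleCollection <- function(nQuant = 2, nQual = 1, n = 8, seed = 99) {
  set.seed(seed)
  g <- randomGenotypeMatrix(n, 4, missingRate = 0)
  ids <- accessionIds(g)
  values <- data.frame(row.names = ids)
  traits <- data.frame(name = character(0), kind = character(0))
  classLabels <- list()
  for (q in seq_len(nQuant)) {
    nm <- paste0("qt", q)
    values[[nm]] <- runif(n, 10, 20)
    traits <- rbind(traits, data.frame(name = nm, kind = "quantitative"))
  }
  for (q in seq_len(nQual)) {
    nm <- paste0("ct", q)
    labels <- paste0(nm, "_", letters[1:3])
    values[[nm]] <- sample(labels, n, replace = TRUE)
    traits <- rbind(traits, data.frame(name = nm, kind = "qualitative"))
    classLabels[[nm]] <- labels
  }
  ph <- PhenotypeTable(values, traits, classLabels)
  mergeCollection(g, ph, PassportTable(ids, rep("spX", n)))
}
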