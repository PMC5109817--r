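.asDistMatrix <- function(D) {
  d <- if (is.list(D) && !is.null(D$d)) D$d else as.matrix(D)
  if (!isSymmetric(unname(d))) .stopf("dissimilarity matrix must be symmetric")
  if (any(!is.finite(d))) .stopf("dissimilarity matrix has non-finite entries")
  d
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Classic Saitou-Nei neighbor joining (Studier-Keppler Q-criterion,
#' unweighted distance update), via [ape::nj()]. Negative branch lengths
#' are clamped to zero; the number clamped is reported in the tree's
#' `"nNegativeClamped"` attribute.
#'
#' @param D output of [manhattanDissimilarity()], a symmetric matrix, or a
#'   `dist` object; at least 3 accessions.
#' @return an unrooted `phylo` tree with attribute `"method" = "nj"`.
#' @export
njTree <- function(D) {
  d <- .asDistMatrix(D)
  if (nrow(d) < 3L) .stopf("neighbor joining needs at least 3 accessions")
  tree <- ape::nj(stats::as.dist(d))
  neg <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "method") <- "nj"
  attr(tree, "nNegativeClamped") <- neg
  tree
}

#' UPGMA tree (average-linkage hierarchical clustering)
#'
#' Average-linkage agglomeration of the dissimilarity matrix; merge heights
#' are non-decreasing and the resulting tree is ultrametric. The underlying
#' `hclust` object is kept in the `"hclust"` attribute so that [cutTree()]
#' can extract flat clusters.
#'
#' @inheritParams njTree
#' @return a rooted ultrametric `phylo` tree with attribute
#'   `"method" = "upgma"`.
#' @export
upgmaTree <- function(D) {
  d <- .asDistMatrix(D)
  if (nrow(d) < 2L) .stopf("need at least 2 accessions")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "method") <- "upgma"
  attr(tree, "hclust") <- hc
  tree
}

#' Cut an UPGMA tree into k flat clusters
#'
#' Undoes the k-1 highest merges of the average-linkage dendrogram. Only
#' rooted UPGMA trees can be cut; a neighbor-joining tree is unrooted and
#' has no cut height, so passing one is an error.
#'
#' @param tree a tree from [upgmaTree()].
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return a named integer vector of cluster labels (1..k) keyed by
#'   accession id, with attributes `"k"` and `"provenance" = "tree-cut"`.
#' @export
cutTree <- function(tree, k) {
  if (!identical(attr(tree, "method"), "upgma"))
    .stopf("cutTree requires an UPGMA tree (NJ trees are unrooted); use upgmaTree()")
  hc <- attr(tree, "hclust")
  if (k < 1L || k > length(hc$labels)) .stopf("k must be in [1, n_leaves]")
  cl <- stats::cutree(hc, k = k)
  attr(cl, "k") <- k
  attr(cl, "provenance") <- "tree-cut"
  cl
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and keeps coordinates on axes
#' with positive eigenvalues. Percent variance per axis is its eigenvalue
#' over the sum of positive eigenvalues.
#'
#' @inheritParams njTree
#' @param nAxes number of axes to return (truncated with a warning if it
#'   exceeds the number of positive eigenvalues).
#' @return list with `coordinates` (ids x axes), `pctVariance`
#'   (non-increasing) and `eigenvalues`.
#' @export
runPcoa <- function(D, nAxes = 2) {
  d <- .asDistMatrix(D)
  if (nrow(d) < 3L) .stopf("PCoA needs at least 3 accessions")
  mds <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = nrow(d) - 1L, eig = TRUE))
  eig <- mds$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (nAxes > length(pos)) {
    .warnf("requested %d axes but only %d positive eigenvalues; truncating",
           nAxes, length(pos))
    nAxes <- length(pos)
  }
  keep <- pos[seq_len(nAxes)]
  coords <- mds$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  list(coordinates = coords,
       pctVariance = 100 * eig[keep] / sum(eig[pos]),
       eigenvalues = eig[pos])
}

.newickLabel <- function(lab) {
  if (grepl("[][():,;' \t\n]", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

.newickString <- function(tree) {
  nTip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  recurse <- function(node) {
    if (node <= nTip) return(.newickLabel(tree$tip.label[node]))
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      bl <- if (!is.null(tree$edge.length))
        sprintf(":%.10g", tree$edge.length[e]) else ""
      paste0(recurse(child), bl)
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  paste0(recurse(root), ";")
}

#' Export / import trees in Newick format
#'
#' Export writes standard Newick with branch lengths; labels containing
#' whitespace or Newick metacharacters are single-quoted, so they round-trip
#' intact through [importNewick()] (which delegates parsing to
#' [ape::read.tree()] and strips the quotes again).
#'
#' @param tree a `phylo` tree.
#' @param path file path.
#' @return `path` invisibly (export) or a `phylo` tree (import).
#' @export
exportNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tryCatch(writeLines(.newickString(tree), path),
           error = function(e) .stopf("cannot write Newick to %s: %s", path,
                                      conditionMessage(e)))
  invisible(path)
}

#' @rdname exportNewick
#' @export
importNewick <- function(path) {
  if (!file.exists(path)) .stopf("Newick file not found: %s", path)
  txt <- paste(readLines(path), collapse = "")
  # protect whitespace inside quoted labels from the tokenizer, which
  # strips all whitespace before parsing
  txt <- vapply(strsplit(txt, "'", fixed = TRUE)[[1L]], identity, "")
  inQuote <- seq_along(txt) %% 2 == 0  # segments between odd/even quotes
  txt[inQuote] <- gsub(" ", "\a", txt[inQuote], fixed = TRUE)
  tree <- ape::read.tree(text = paste(txt, collapse = "'"))
  lab <- gsub("\a", " ", tree$tip.label, fixed = TRUE)
  quoted <- grepl("^'.*'$", lab)
  lab[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[quoted]))
  tree$tip.label <- lab
  tree
}
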