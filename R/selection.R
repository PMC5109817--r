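#' Greedy maximum-coverage core selection (advanced M strategy)
#'
#' Deterministic greedy cover of every class in a
#' [ClassificationTable-class]: at each step every unselected accession is
#' scored by the number of still-uncovered classes it carries and the best
#' is selected. Ties are broken by (a) the larger sum of `1 / carrier count`
#' over the uncovered classes the accession carries, preferring carriers of
#' rare classes, then (b) the lexicographically smallest accession id.
#' After full coverage, a backward redundancy pass visits the selected
#' accessions in selection order and drops any whose removal leaves all
#' classes covered. The result is independent of accession input order.
#'
#' @param ct a [ClassificationTable-class] with at least one class.
#' @param strategy,basis provenance tags recorded on the result.
#' @return a [CoreSet-class] covering 100% of the table's classes.
#' @export
mStrategySelect <- function(ct, strategy = "custom", basis = "custom") {
  stopifnot(is(ct, "ClassificationTable"))
  M <- ct@membership
  if (ncol(M) == 0L) .stopf("classification table has no classes")
  if (any(colSums(M) == 0))
    .stopf("internal error: class with no carrier (input not pruned)")
  carriers <- colSums(M)
  rarity <- 1 / carriers
  uncovered <- rep(TRUE, ncol(M))
  remaining <- rownames(M)
  selected <- character(0)
  while (any(uncovered)) {
    sub <- M[remaining, uncovered, drop = FALSE]
    gain <- rowSums(sub)
    best <- which(gain == max(gain))
    if (length(best) > 1L) {
      rar <- as.numeric(sub[best, , drop = FALSE] %*% rarity[uncovered])
      best <- best[rar == max(rar)]
    }
    pick <- sort(remaining[best])[1L]
    selected <- c(selected, pick)
    uncovered <- uncovered & !M[pick, ]
    remaining <- setdiff(remaining, pick)
  }
  # backward redundancy elimination, in selection order
  for (id in selected) {
    rest <- setdiff(selected, id)
    if (length(rest) > 0L &&
        all(colSums(M[rest, , drop = FALSE]) > 0))
      selected <- rest
  }
  new("CoreSet", strategy = strategy, ids = selected,
      clusterOf = character(0), classesCovered = ncol(M),
      classesTotal = ncol(M), basis = basis)
}

#' Stratified M-strategy selection over clusters
#'
#' Builds a per-cluster [ClassificationTable-class] (classes observed within
#' that cluster; Sturges bins recomputed on cluster data), runs
#' [mStrategySelect()] in each cluster, and returns the deduplicated union
#' with per-cluster provenance (first cluster kept on duplicates). A
#' singleton cluster contributes its sole accession, with a warning.
#' Coverage is accounted against the classes the strategy targeted: the
#' union of the per-cluster tables, with marker and qualitative-trait
#' classes deduplicated globally and quantitative Sturges bins counted per
#' cluster (bins are recomputed within each stratum, so a "global" bin is
#' not a meaningful unit of stratified coverage).
#'
#' @param collection a [GermplasmCollection-class].
#' @param clusters named vector of cluster labels keyed by accession id;
#'   must cover the accessions to select from.
#' @param basis `"genotype"`, `"phenotype"`, or `"both"`.
#' @param strategy provenance tag recorded on the result.
#' @return a [CoreSet-class].
#' @export
stratifiedSelect <- function(collection, clusters,
                             basis = c("genotype", "phenotype", "both"),
                             strategy = "custom") {
  basis <- match.arg(basis)
  if (is.null(names(clusters))) .stopf("clusters must be named by accession id")
  ids <- intersect(rownames(collection@genotypes@calls), names(clusters))
  if (length(ids) == 0L) .stopf("clusters cover no genotyped accession")
  labels <- as.character(clusters[ids])
  selected <- character(0)
  clusterOf <- character(0)
  targeted <- character(0)   # state keys the per-cluster selections target
  covered <- character(0)    # those verified covered by the selected entries
  for (k in unique(labels)) {
    members <- ids[labels == k]
    ctk <- suppressWarnings(
      buildClassification(collection, basis = basis, subset = members))
    if (length(members) == 1L) {
      .warnf("cluster '%s' is a singleton; its sole accession is selected", k)
      pick <- members
    } else {
      pick <- mStrategySelect(ctk)@ids
    }
    st <- ctk@states
    keys <- ifelse(st$source == "quant-trait",
                   paste(k, st$variable, st$class, sep = "::"),
                   paste(st$variable, st$class, sep = "::"))
    targeted <- c(targeted, keys)
    isCov <- colSums(ctk@membership[pick, , drop = FALSE]) > 0
    covered <- c(covered, keys[isCov])
    newIds <- setdiff(pick, selected)
    selected <- c(selected, newIds)
    clusterOf <- c(clusterOf, setNames(rep(k, length(newIds)), newIds))
  }
  new("CoreSet", strategy = strategy, ids = selected, clusterOf = clusterOf,
      classesCovered = length(unique(covered)),
      classesTotal = length(unique(targeted)),
      basis = basis)
}

#' Run one of the five core-sampling strategies
#'
#' Dispatches to the right basis/stratification combination:
#' \describe{
#'   \item{Gcc}{genotype classes, whole collection}
#'   \item{Ggcc}{genotype classes, selected per cluster}
#'   \item{Pcc}{phenotype classes, whole collection}
#'   \item{G+Pcc}{genotype + phenotype classes, whole collection}
#'   \item{Gg+Pcc}{genotype + phenotype classes, selected per cluster}
#' }
#'
#' @param collection a [GermplasmCollection-class].
#' @param strategy one of `"Gcc"`, `"Ggcc"`, `"Pcc"`, `"G+Pcc"`, `"Gg+Pcc"`.
#' @param clusters named cluster labels; required for `Ggcc` and `Gg+Pcc`.
#' @param subset accession ids eligible for selection (default: all; for the
#'   stratified strategies the clustered accessions).
#' @return a [CoreSet-class] tagged with the strategy.
#' @export
runStrategy <- function(collection,
                        strategy = c("Gcc", "Ggcc", "Pcc", "G+Pcc", "Gg+Pcc"),
                        clusters = NULL, subset = NULL) {
  strategy <- match.arg(strategy)
  stratified <- strategy %in% c("Ggcc", "Gg+Pcc")
  basis <- switch(strategy, Gcc = "genotype", Ggcc = "genotype",
                  Pcc = "phenotype", `G+Pcc` = "both", `Gg+Pcc` = "both")
  if (stratified) {
    if (is.null(clusters))
      .stopf("strategy '%s' needs cluster labels (see cutTree)", strategy)
    if (!is.null(subset)) clusters <- clusters[intersect(names(clusters), subset)]
    stratifiedSelect(collection, clusters, basis = basis, strategy = strategy)
  } else {
    ct <- buildClassification(collection, basis = basis, subset = subset)
    mStrategySelect(ct, strategy = strategy, basis = basis)
  }
}

#' Write a core set as csv
#'
#' @param core a [CoreSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoreSet <- function(core, path) {
  stopifnot(is(core, "CoreSet"))
  cl <- if (length(core@clusterOf)) unname(core@clusterOf[core@ids]) else NA
  utils::write.csv(data.frame(accession = core@ids, strategy = core@strategy,
                              cluster = cl, stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
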