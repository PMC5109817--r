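#' Allele frequencies per marker
#'
#' Each non-missing diploid call contributes two allele copies. Markers with
#' no non-missing call in the subset are flagged absent and carry no
#' frequencies.
#'
#' @param g a [GenotypeMatrix-class].
#' @param subset accession ids to use (default: all).
#' @return a list with `freq` (named list per marker of named frequency
#'   vectors summing to 1), `nCopies` (non-missing allele copies per marker)
#'   and `absent` (marker ids with no data).
#' @export
alleleFrequencies <- function(g, subset = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  ids <- subset %||% rownames(g@calls)
  if (length(ids) == 0L) .stopf("empty accession subset")
  bad <- setdiff(ids, rownames(g@calls))
  if (length(bad)) .stopf("unknown accession(s): %s", paste(bad, collapse = ", "))
  calls <- g@calls[ids, , drop = FALSE]
  freq <- vector("list", ncol(calls))
  names(freq) <- colnames(calls)
  nCopies <- setNames(numeric(ncol(calls)), colnames(calls))
  for (m in colnames(calls)) {
    obs <- calls[, m]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) next
    counts <- table(unlist(strsplit(obs, "/", fixed = TRUE)))
    nCopies[m] <- sum(counts)
    freq[[m]] <- as.numeric(counts) / sum(counts)
    names(freq[[m]]) <- names(counts)
  }
  absent <- names(freq)[vapply(freq, is.null, TRUE)]
  list(freq = freq[!vapply(freq, is.null, TRUE)],
       nCopies = nCopies[nCopies > 0], absent = absent)
}

#' Expected heterozygosity (gene diversity)
#'
#' Per marker `H_E = 1 - sum(p_i^2)` on allele frequencies, with no
#' small-sample correction; the group value is the unweighted mean over
#' markers with data.
#'
#' @param freqs output of [alleleFrequencies()].
#' @return list with `perMarker` (named numeric) and `mean`.
#' @export
expectedHet <- function(freqs) {
  per <- vapply(freqs$freq, function(p) 1 - sum(p^2), 0)
  list(perMarker = per, mean = mean(per))
}

#' Observed heterozygosity per marker
#'
#' Per marker: heterozygous calls / non-missing calls; group value is the
#' mean over markers with data.
#'
#' @inheritParams alleleFrequencies
#' @return list with `perMarker` and `mean`.
#' @export
observedHet <- function(g, subset = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  ids <- subset %||% rownames(g@calls)
  if (length(ids) == 0L) .stopf("empty accession subset")
  calls <- g@calls[ids, , drop = FALSE]
  hetM <- matrix(.isHet(as.vector(calls)), nrow = nrow(calls),
                 dimnames = dimnames(calls))
  nObs <- colSums(!is.na(hetM))
  per <- ifelse(nObs > 0, colSums(hetM, na.rm = TRUE) / nObs, NA_real_)
  list(perMarker = per, mean = mean(per, na.rm = TRUE))
}

#' Polymorphic information content (Botstein form)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Always `<= H_E`, with
#' equality only for a monomorphic marker (both 0).
#'
#' @inheritParams expectedHet
#' @return list with `perMarker` and `mean`.
#' @export
markerPic <- function(freqs) {
  per <- vapply(freqs$freq, function(p) {
    s2 <- sum(p^2)
    1 - s2 - (s2^2 - sum(p^4))  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  }, 0)
  list(perMarker = per, mean = mean(per))
}

#' Shannon's information index of diversity
#'
#' `I = -sum(f_c * ln(f_c))` over class frequencies, with `0 ln 0 := 0` and
#' the natural logarithm throughout.
#'
#' @param classFreqs nonnegative frequencies summing to 1 (or counts, which
#'   are normalized).
#' @return the index `I >= 0`.
#' @export
shannonIndex <- function(classFreqs) {
  if (any(classFreqs < 0)) .stopf("frequencies must be nonnegative")
  s <- sum(classFreqs)
  if (s <= 0) .stopf("frequencies must not all be zero")
  .shannonFromCounts(classFreqs / s)
}

#' Maximum Shannon index for a class count
#'
#' `I_max = ln(n_classes)`, the Shannon index of a uniform distribution over
#' the classes.
#'
#' @param nClasses number of classes (>= 1).
#' @return `ln(nClasses)`.
#' @export
iMax <- function(nClasses) {
  if (any(nClasses < 1)) .stopf("nClasses must be >= 1")
  log(nClasses)
}

#' Pielou's evenness
#'
#' `J' = I / ln(n_classes)`; 1 when class frequencies are uniform.
#'
#' @param I Shannon index.
#' @param nClasses number of classes (>= 2; with a single class evenness is
#'   undefined).
#' @return evenness in \[0, 1\].
#' @export
pielouEvenness <- function(I, nClasses) {
  if (any(nClasses < 2)) .stopf("evenness undefined for fewer than 2 classes")
  I / log(nClasses)
}

# Shannon index over observed genotype patterns, averaged over markers
.meanPatternShannon <- function(calls) {
  per <- apply(calls, 2L, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) return(NA_real_)
    .shannonFromCounts(table(obs))
  })
  mean(per, na.rm = TRUE)
}

#' Groupwise diversity summary
#'
#' Per group (species, cluster, or the whole collection): accession count,
#' mean observed and expected heterozygosity, mean PIC, and mean Shannon
#' index `I` over markers. For markers, Shannon classes are the observed
#' genotype patterns (e.g. `A/A`, `A/B`, `B/B`).
#'
#' @param collection a [GermplasmCollection-class] (or bare
#'   [GenotypeMatrix-class] when `grouping` is a named vector or `"total"`).
#' @param grouping `"total"`, `"species"` (requires a passport table), or a
#'   named vector of group labels keyed by accession id.
#' @return data.frame with one row per group plus a `"total"` row when
#'   grouping partitions the collection. Groups of size zero are skipped
#'   with a warning.
#' @export
groupDiversity <- function(collection, grouping = "total") {
  g <- if (is(collection, "GermplasmCollection")) collection@genotypes
       else collection
  stopifnot(is(g, "GenotypeMatrix"))
  ids <- rownames(g@calls)
  labels <- if (identical(grouping, "total")) {
    setNames(rep("total", length(ids)), ids)
  } else if (identical(grouping, "species")) {
    if (!is(collection, "GermplasmCollection") || is.null(collection@passport))
      .stopf("grouping by species requires a passport table")
    pp <- collection@passport@data
    setNames(pp$species, pp$accession)[ids]
  } else {
    if (is.null(names(grouping))) .stopf("grouping vector must be named by accession id")
    setNames(as.character(grouping)[match(ids, names(grouping))], ids)
  }
  labels <- labels[!is.na(labels)]
  groups <- split(names(labels), labels)
  oneRow <- function(label, members) {
    fr <- alleleFrequencies(g, members)
    data.frame(group = label, n = length(members),
               hO = observedHet(g, members)$mean,
               hE = expectedHet(fr)$mean,
               pic = markerPic(fr)$mean,
               I = .meanPatternShannon(g@calls[members, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(groups), function(lb) oneRow(lb, groups[[lb]]))
  out <- do.call(rbind, rows)
  if (!identical(grouping, "total") && length(groups) > 1L)
    out <- rbind(out, oneRow("total", names(labels)))
  rownames(out) <- NULL
  out
}

#' Per-cluster differentiation (Wright-style F_ST proxy)
#'
#' Per marker, `H_T` is the expected heterozygosity of the pooled allele
#' frequencies and `H_Sk` that of cluster `k`'s frequencies;
#' `F_STk = mean over markers of (H_T - H_Sk)/H_T`, skipping markers with
#' `H_T = 0`. Negative estimates are reported as-is, never clipped.
#'
#' @param g a [GenotypeMatrix-class].
#' @param clusters named vector of cluster labels keyed by accession id
#'   (accessions absent from it are ignored).
#' @return data.frame with one row per cluster (`cluster`, `n`, `hE`, `I`,
#'   `fst`) plus a `"total"` row carrying pooled `hE`/`I` and the unweighted
#'   mean `fst`.
#' @export
fstPerCluster <- function(g, clusters) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (is.null(names(clusters))) .stopf("clusters must be named by accession id")
  ids <- intersect(rownames(g@calls), names(clusters))
  labels <- as.character(clusters[ids])
  groups <- split(ids, labels)
  if (length(groups) < 2L) .stopf("need at least 2 clusters")
  pooled <- alleleFrequencies(g, ids)
  hT <- expectedHet(pooled)$perMarker
  if (all(hT == 0)) .stopf("all markers monomorphic; F_ST undefined")
  rows <- lapply(names(groups), function(k) {
    members <- groups[[k]]
    frk <- alleleFrequencies(g, members)
    hSk <- expectedHet(frk)$perMarker
    shared <- intersect(names(hT)[hT > 0], names(hSk))
    fst <- mean((hT[shared] - hSk[shared]) / hT[shared])
    data.frame(cluster = k, n = length(members),
               hE = expectedHet(frk)$mean,
               I = .meanPatternShannon(g@calls[members, , drop = FALSE]),
               fst = fst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(cluster = "total", n = length(ids),
                      hE = expectedHet(pooled)$mean,
                      I = .meanPatternShannon(g@calls[ids, , drop = FALSE]),
                      fst = mean(out$fst), stringsAsFactors = FALSE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
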