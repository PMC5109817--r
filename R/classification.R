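#' Sturges bin edges for a quantitative trait
#'
#' `k = ceiling(1 + log2(n))` equal-width bins over \[min, max\] of the
#' non-missing values. Values falling on an internal edge belong to the
#' lower bin; the maximum belongs to the top bin. A constant trait yields a
#' single degenerate class, with a warning.
#'
#' @param values numeric vector (NAs ignored); at least 2 non-missing values.
#' @return numeric vector of k+1 bin edges, with attribute `"k"`.
#' @export
sturgesBins <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) .stopf("need at least 2 non-missing values")
  if (any(!is.finite(v))) .stopf("values must be finite")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    .warnf("constant trait: single degenerate class")
    edges <- c(lo, hi)
    attr(edges, "k") <- 1L
    return(edges)
  }
  k <- ceiling(1 + log2(length(v)))
  edges <- seq(lo, hi, length.out = k + 1)
  attr(edges, "k") <- as.integer(k)
  edges
}

# assign values to Sturges bins: (e_{i-1}, e_i], first bin closed at min
.binAssign <- function(values, edges) {
  if (length(edges) == 2L && edges[1L] == edges[2L])
    return(ifelse(is.na(values), NA_integer_, 1L))
  idx <- findInterval(values, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[!is.na(values) & values == edges[1L]] <- 1L
  idx[!is.na(idx) & idx > length(edges) - 1L] <- NA_integer_  # above max: no class
  idx[!is.na(values) & values < edges[1L]] <- NA_integer_
  idx
}

#' Build the class-membership substrate for M-strategy selection
#'
#' Marker variables contribute one class per observed allele; an accession
#' carries every allele present in its call (a heterozygote carries two
#' classes of that marker). Qualitative traits contribute their observed
#' categories; quantitative traits contribute Sturges bins computed on the
#' requested subset. Missing values carry no state. Classes observed in no
#' accession of the subset are pruned.
#'
#' @param collection a [GermplasmCollection-class].
#' @param basis `"genotype"`, `"phenotype"`, or `"both"`.
#' @param subset accession ids (default: all genotyped accessions).
#' @return a [ClassificationTable-class].
#' @export
buildClassification <- function(collection,
                                basis = c("genotype", "phenotype", "both"),
                                subset = NULL) {
  stopifnot(is(collection, "GermplasmCollection"))
  basis <- match.arg(basis)
  ids <- subset %||% rownames(collection@genotypes@calls)
  bad <- setdiff(ids, rownames(collection@genotypes@calls))
  if (length(bad)) .stopf("unknown accession(s): %s", paste(bad, collapse = ", "))
  if (basis %in% c("phenotype", "both") && is.null(collection@phenotypes))
    .stopf("basis '%s' requires a phenotype table", basis)

  cols <- list()       # named logical vectors over ids
  states <- list()     # data.frame rows
  variables <- list()
  binEdges <- list()

  if (basis %in% c("genotype", "both")) {
    calls <- collection@genotypes@calls[ids, , drop = FALSE]
    for (m in colnames(calls)) {
      al <- .callAlleles(calls[, m])
      obsAlleles <- sort(unique(c(al$a1[!is.na(al$a1)], al$a2[!is.na(al$a2)])))
      if (length(obsAlleles) == 0L) next
      for (a in obsAlleles) {
        key <- paste0(m, "::", a)
        carry <- (!is.na(al$a1) & al$a1 == a) | (!is.na(al$a2) & al$a2 == a)
        cols[[key]] <- carry
        states[[key]] <- data.frame(variable = m, class = a,
                                    source = "marker", stringsAsFactors = FALSE)
      }
      variables[[m]] <- data.frame(name = m, source = "marker",
                                   nClasses = length(obsAlleles),
                                   stringsAsFactors = FALSE)
    }
  }

  if (basis %in% c("phenotype", "both")) {
    ph <- collection@phenotypes
    phIds <- intersect(ids, rownames(ph@values))
    vals <- ph@values[phIds, , drop = FALSE]
    for (i in seq_len(nrow(ph@traits))) {
      nm <- ph@traits$name[i]
      v <- vals[[nm]]
      if (ph@traits$kind[i] == "qualitative") {
        obsClasses <- sort(unique(v[!is.na(v)]))
        if (length(obsClasses) == 0L) next
        for (cl in obsClasses) {
          key <- paste0(nm, "::", cl)
          carry <- setNames(rep(FALSE, length(ids)), ids)
          carry[phIds] <- !is.na(v) & v == cl
          cols[[key]] <- unname(carry)
          states[[key]] <- data.frame(variable = nm, class = cl,
                                      source = "qual-trait",
                                      stringsAsFactors = FALSE)
        }
        variables[[nm]] <- data.frame(name = nm, source = "qual-trait",
                                      nClasses = length(obsClasses),
                                      stringsAsFactors = FALSE)
      } else {
        if (sum(!is.na(v)) < 2L) next
        edges <- suppressWarnings(sturgesBins(v))
        binEdges[[nm]] <- edges
        bins <- .binAssign(v, edges)
        obsBins <- sort(unique(bins[!is.na(bins)]))
        for (b in obsBins) {
          key <- paste0(nm, "::bin", b)
          carry <- setNames(rep(FALSE, length(ids)), ids)
          carry[phIds] <- !is.na(bins) & bins == b
          cols[[key]] <- unname(carry)
          states[[key]] <- data.frame(variable = nm, class = paste0("bin", b),
                                      source = "quant-trait",
                                      stringsAsFactors = FALSE)
        }
        variables[[nm]] <- data.frame(name = nm, source = "quant-trait",
                                      nClasses = length(obsBins),
                                      stringsAsFactors = FALSE)
      }
    }
  }

  if (length(cols) == 0L) .stopf("no classes observed for basis '%s'", basis)
  membership <- do.call(cbind, cols)
  rownames(membership) <- ids
  new("ClassificationTable", membership = membership,
      states = do.call(rbind, c(states, list(make.row.names = FALSE))),
      variables = do.call(rbind, c(variables, list(make.row.names = FALSE))),
      binEdges = binEdges)
}
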