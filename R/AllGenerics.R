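#' Accessors for package classes
#'
#' `accessionIds()` and `markerIds()` return the ordered identifiers of a
#' [GenotypeMatrix-class] (or of the genotype panel of a
#' [GermplasmCollection-class]); `genotypeCalls()` the normalized call matrix;
#' `markerAlleles()` the per-marker allele sets; `nAccessions()`/`nMarkers()`
#' the dimensions; `nMissing()` the count of missing calls; `coreIds()` and
#' `coreStrategy()` the contents of a [CoreSet-class]; `retainedIds()` the
#' accessions passing a [QCReport-class].
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("markerAlleles", function(x) standardGeneric("markerAlleles"))
#' @rdname accessors
#' @export
setGeneric("nAccessions", function(x) standardGeneric("nAccessions"))
#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setGeneric("nMissing", function(x) standardGeneric("nMissing"))
#' @rdname accessors
#' @export
setGeneric("coreIds", function(x) standardGeneric("coreIds"))
#' @rdname accessors
#' @export
setGeneric("coreStrategy", function(x) standardGeneric("coreStrategy"))
#' @rdname accessors
#' @export
setGeneric("retainedIds", function(x) standardGeneric("retainedIds"))

#' @rdname accessors
setMethod("accessionIds", "GenotypeMatrix", function(x) rownames(x@calls))
#' @rdname accessors
setMethod("accessionIds", "GermplasmCollection",
          function(x) rownames(x@genotypes@calls))
#' @rdname accessors
setMethod("accessionIds", "PhenotypeTable", function(x) rownames(x@values))
#' @rdname accessors
setMethod("accessionIds", "PassportTable", function(x) x@data$accession)
#' @rdname accessors
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@calls))
#' @rdname accessors
setMethod("markerIds", "GermplasmCollection",
          function(x) colnames(x@genotypes@calls))
#' @rdname accessors
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("genotypeCalls", "GermplasmCollection", function(x) x@genotypes@calls)
#' @rdname accessors
setMethod("markerAlleles", "GenotypeMatrix", function(x) x@markerAlleles)
#' @rdname accessors
setMethod("nAccessions", "GenotypeMatrix", function(x) nrow(x@calls))
#' @rdname accessors
setMethod("nAccessions", "GermplasmCollection", function(x) nrow(x@genotypes@calls))
#' @rdname accessors
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@calls))
#' @rdname accessors
setMethod("nMarkers", "GermplasmCollection", function(x) ncol(x@genotypes@calls))
#' @rdname accessors
setMethod("nMissing", "GenotypeMatrix", function(x) sum(is.na(x@calls)))
#' @rdname accessors
setMethod("coreIds", "CoreSet", function(x) x@ids)
#' @rdname accessors
setMethod("coreStrategy", "CoreSet", function(x) x@strategy)
#' @rdname accessors
setMethod("retainedIds", "QCReport", function(x) x@retainedIds)

#' Subset a GenotypeMatrix or GermplasmCollection by accessions/markers
#'
#' @param x the object.
#' @param i accession ids or indices.
#' @param j marker ids or indices (GenotypeMatrix only).
#' @param ... ignored.
#' @param drop ignored; subsetting never drops dimensions.
#' @return an object of the same class.
#' @aliases [,GenotypeMatrix,ANY,ANY,ANY-method [,GermplasmCollection,ANY,ANY,ANY-method
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  calls <- x@calls[i, j, drop = FALSE]
  GenotypeMatrix(calls, markerAlleles = x@markerAlleles[colnames(calls)])
})

#' @rdname sub-GenotypeMatrix-ANY-ANY-ANY-method
#' @export
setMethod("[", "GermplasmCollection", function(x, i, j, ..., drop = FALSE) {
  g <- x@genotypes[i, ]
  ids <- rownames(g@calls)
  ph <- x@phenotypes
  if (!is.null(ph)) {
    keep <- intersect(ids, rownames(ph@values))
    ph <- new("PhenotypeTable", values = ph@values[keep, , drop = FALSE],
              traits = ph@traits, classLabels = ph@classLabels)
  }
  pp <- x@passport
  if (!is.null(pp)) {
    d <- pp@data[pp@data$accession %in% ids, , drop = FALSE]
    rownames(d) <- NULL
    pp <- new("PassportTable", data = d)
  }
  ho <- x@holdout
  if (!is.null(ho)) ho <- ho[intersect(ids, rownames(ho@calls)), ]
  new("GermplasmCollection", genotypes = g, phenotypes = ph, passport = pp,
      holdout = ho)
})

setMethod("show", "GenotypeMatrix", function(object) {
  nAl <- lengths(object@markerAlleles)
  cat(sprintf("GenotypeMatrix: %d accessions x %d markers (%d biallelic, %d multi-allelic), %d missing calls\n",
              nrow(object@calls), ncol(object@calls),
              sum(nAl <= 2), sum(nAl > 2), sum(is.na(object@calls))))
})

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d accessions x %d traits (%d qualitative, %d quantitative)\n",
              nrow(object@values), nrow(object@traits),
              sum(object@traits$kind == "qualitative"),
              sum(object@traits$kind == "quantitative")))
})

setMethod("show", "PassportTable", function(object) {
  cat(sprintf("PassportTable: %d accessions, %d species, %d origins\n",
              nrow(object@data), length(unique(object@data$species)),
              length(unique(object@data$origin))))
})

setMethod("show", "GermplasmCollection", function(object) {
  cat("GermplasmCollection\n")
  cat("  "); show(object@genotypes)
  if (!is.null(object@phenotypes)) { cat("  "); show(object@phenotypes) }
  if (!is.null(object@passport)) { cat("  "); show(object@passport) }
  if (!is.null(object@holdout))
    cat(sprintf("  hold-out markers: %d\n", ncol(object@holdout@calls)))
})

setMethod("show", "QCReport", function(object) {
  tab <- object@table
  cat(sprintf("QCReport: %d accessions; %d flagged hybrid (H_O > %.2f), %d high-missing (> %d), %d retained\n",
              nrow(tab), sum(tab$hybrid), object@hetThreshold,
              sum(tab$highMissing), object@maxMissing,
              length(object@retainedIds)))
})

setMethod("show", "ClassificationTable", function(object) {
  cat(sprintf("ClassificationTable: %d accessions x %d classes over %d variables (%s)\n",
              nrow(object@membership), ncol(object@membership),
              nrow(object@variables),
              paste(sprintf("%s: %d", names(table(object@variables$source)),
                            table(object@variables$source)), collapse = ", ")))
})

setMethod("show", "CoreSet", function(object) {
  cat(sprintf("CoreSet [%s, basis=%s]: %d entries covering %d/%d classes\n",
              object@strategy, object@basis, length(object@ids),
              object@classesCovered, object@classesTotal))
})

setMethod("show", "EvaluationReport", function(object) {
  a <- object@aggregates
  cat(sprintf("EvaluationReport: core %d of %d (%.1f%%)\n", object@nCore,
              object@nEntire, 100 * object@nCore / object@nEntire))
  if (length(a))
    cat(sprintf("  MD%% = %.2f  CR%% = %.2f  VD%% = %.2f  VR%% = %.2f\n",
                a$MD, a$CR, a$VD, a$VR))
  if (length(object@categorical))
    cat(sprintf("  I = %.2f (entire %.2f)  J' = %.2f (entire %.2f)\n",
                object@categorical$core$I, object@categorical$entire$I,
                object@categorical$core$J, object@categorical$entire$J))
  cat(sprintf("  representative (MD%% < 20 and CR%% > 80): %s\n",
              if (isTRUE(object@verdict)) "yes" else "no"))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d accessions, %d markers, K=%d, %d species, %d+%d traits, %d hold-out markers, seed=%s\n",
              object@nAccessions, object@nMarkers, object@K,
              length(object@speciesCounts), object@nTraitsQuant,
              object@nTraitsQual, object@nHoldoutMarkers,
              format(object@seed)))
})

setMethod("show", "TruthRecord", function(object) {
  cat(sprintf("TruthRecord: %d accessions, %d clusters, %d planted F1 hybrids\n",
              length(object@cluster), nlevels(factor(object@cluster)),
              sum(object@hybrid)))
})
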