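#' Per-accession observed heterozygosity
#'
#' Fraction of heterozygous calls among an accession's non-missing calls.
#' The denominator excludes missing calls, so missingness is not penalized
#' twice (it has its own filter in [applyQC()]).
#'
#' @param g a [GenotypeMatrix-class].
#' @param id accession id.
#' @return a fraction in \[0, 1\].
#' @export
accessionObservedHet <- function(g, id) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (!id %in% rownames(g@calls)) .stopf("unknown accession '%s'", id)
  calls <- g@calls[id, ]
  het <- .isHet(calls)
  nObs <- sum(!is.na(het))
  if (nObs == 0L) .stopf("accession '%s' has no non-missing calls; H_O undefined", id)
  sum(het, na.rm = TRUE) / nObs
}

#' Accession-level quality control: F1-hybrid and missingness filters
#'
#' Flags as putative F1 hybrids all accessions whose observed heterozygosity
#' strictly exceeds `hetThreshold` (in a predominantly selfing germplasm,
#' high H_O marks planted F1s), and as high-missing all accessions with
#' strictly more than `maxMissing` missing calls. Both inequalities are
#' strict: an accession at exactly the threshold is retained. The two flags
#' are independent; retained accessions carry neither.
#'
#' @param g a [GenotypeMatrix-class].
#' @param hetThreshold heterozygosity cut-off (default 0.3).
#' @param maxMissing missing-call cut-off (default 7; i.e. 8 or more missing
#'   of a 48-marker panel excludes).
#' @return a [QCReport-class].
#' @examples
#' sim <- simulateCollection(simulationConfig(60, nMarkers = 24, K = 2,
#'                                            hybridFraction = 0.1, seed = 7))
#' qc <- applyQC(sim$collection@genotypes)
#' qc
#' @export
applyQC <- function(g, hetThreshold = 0.3, maxMissing = 7) {
  stopifnot(is(g, "GenotypeMatrix"))
  calls <- g@calls
  hetM <- matrix(.isHet(as.vector(calls)), nrow = nrow(calls),
                 dimnames = dimnames(calls))
  nObs <- rowSums(!is.na(hetM))
  hO <- ifelse(nObs > 0, rowSums(hetM, na.rm = TRUE) / nObs, NA_real_)
  missingCount <- rowSums(is.na(calls))
  hybrid <- !is.na(hO) & hO > hetThreshold
  highMissing <- missingCount > maxMissing | nObs == 0
  retained <- !hybrid & !highMissing
  tab <- data.frame(accession = rownames(calls), hO = hO,
                    missingCount = missingCount, hybrid = hybrid,
                    highMissing = highMissing, retained = retained,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(retained)) .warnf("QC retained no accessions")
  new("QCReport", table = tab, retainedIds = tab$accession[retained],
      hetThreshold = hetThreshold, maxMissing = maxMissing)
}

#' Write a QC report as csv
#'
#' @param report a [QCReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(report, path) {
  stopifnot(is(report, "QCReport"))
  utils::write.csv(report@table, path, row.names = FALSE)
  invisible(path)
}
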