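#' Manhattan dissimilarity between accessions
#'
#' Genotypes are encoded as per-allele dosages (0/1/2 copies of each allele).
#' A marker's contribution to the pair (i, j) is
#' `sum over alleles |dosage_i - dosage_j| / 4`, which for a biallelic
#' marker reduces to `|minor-allele dosage difference| / 2` and lies in
#' \[0, 1\] for any ploidy-2 marker. The pairwise dissimilarity is the mean
#' contribution over markers at which both accessions are non-missing
#' (pairwise deletion), so values stay in \[0, 1\] under missingness.
#'
#' @param g a [GenotypeMatrix-class] with at least 2 accessions.
#' @return a list with `d` (symmetric matrix, zero diagonal) and `nShared`
#'   (pairwise co-non-missing marker counts). A pair sharing no markers is
#'   an error naming the pair.
#' @export
manhattanDissimilarity <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  calls <- g@calls
  n <- nrow(calls)
  if (n < 2L) .stopf("need at least 2 accessions")
  obs <- !is.na(calls)
  nShared <- obs %*% t(obs)
  if (any(nShared[upper.tri(nShared)] == 0)) {
    idx <- which(nShared == 0 & upper.tri(nShared), arr.ind = TRUE)[1L, ]
    .stopf("accessions '%s' and '%s' share no non-missing marker",
           rownames(calls)[idx[1L]], rownames(calls)[idx[2L]])
  }
  num <- matrix(0, n, n)
  for (m in seq_len(ncol(calls))) {
    col <- calls[, m]
    alleles <- g@markerAlleles[[m]]
    al <- .callAlleles(col)
    contrib <- matrix(0, n, n)
    for (a in alleles) {
      dos <- (al$a1 == a) + (al$a2 == a)
      dos[is.na(col)] <- 0  # masked below via obs
      contrib <- contrib + abs(outer(dos, dos, "-"))
    }
    # zero out pairs where either is missing at this marker
    mobs <- as.numeric(obs[, m])
    contrib <- contrib * outer(mobs, mobs)
    num <- num + contrib / 4
  }
  d <- num / nShared
  diag(d) <- 0
  dimnames(d) <- list(rownames(calls), rownames(calls))
  list(d = d, nShared = nShared)
}
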