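#' Two-level analysis of molecular variance (AMOVA) from distances
#'
#' Decomposes the total sum of squared pairwise dissimilarities into
#' among-cluster and within-cluster components:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum over clusters of the
#' analogous within-cluster term`, `SS_among = SS_total - SS_within`.
#' Variance components come from the standard expected-mean-square
#' equations (`sigma2_within = MS_within`;
#' `sigma2_among = (MS_among - MS_within) / n0` with
#' `n0 = (N - sum(n_g^2)/N) / (k - 1)`), and
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`. Significance is
#' assessed by permuting cluster labels:
#' `p = (1 + #{Phi_perm >= Phi_obs}) / (nPerm + 1)`.
#'
#' @param D output of [manhattanDissimilarity()], a symmetric matrix, or a
#'   `dist` object.
#' @param clusters named vector of cluster labels keyed by accession id; at
#'   least 2 clusters, each of size >= 2.
#' @param nPerm number of label permutations (default 999).
#' @param seed optional RNG seed for the permutations.
#' @return list with `sigma2Among`, `sigma2Within`, `phiST`, `pctAmong`,
#'   `pctWithin` (summing to 100), `pPerm`, `nPerm`, and the `df`/`SS`/`MS`
#'   table.
#' @export
amova <- function(D, clusters, nPerm = 999, seed = NULL) {
  d <- .asDistMatrix(D)
  if (is.null(names(clusters))) .stopf("clusters must be named by accession id")
  ids <- intersect(rownames(d), names(clusters))
  if (length(ids) < 4L) .stopf("too few accessions for AMOVA")
  d <- d[ids, ids]
  labels <- as.character(clusters[ids])
  sizes <- table(labels)
  if (length(sizes) < 2L) .stopf("need at least 2 clusters")
  if (any(sizes < 2L)) .stopf("every cluster must have at least 2 members")
  d2 <- d^2
  N <- length(ids)
  k <- length(sizes)

  decompose <- function(lab) {
    ssTotal <- sum(d2[upper.tri(d2)]) / N
    ssWithin <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx, drop = FALSE]
      ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ssAmong <- ssTotal - ssWithin
    msAmong <- ssAmong / (k - 1)
    msWithin <- ssWithin / (N - k)
    n0 <- (N - sum(table(lab)^2) / N) / (k - 1)
    s2w <- msWithin
    s2a <- (msAmong - msWithin) / n0
    phi <- s2a / (s2a + s2w)
    list(ssTotal = ssTotal, ssAmong = ssAmong, ssWithin = ssWithin,
         msAmong = msAmong, msWithin = msWithin, s2a = s2a, s2w = s2w,
         phi = phi)
  }

  obs <- decompose(labels)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    phiPerm <- decompose(sample(labels))$phi
    if (phiPerm >= obs$phi) exceed <- exceed + 1L
  }
  pPerm <- (1 + exceed) / (nPerm + 1)
  total <- obs$s2a + obs$s2w
  list(sigma2Among = obs$s2a, sigma2Within = obs$s2w, phiST = obs$phi,
       pctAmong = 100 * obs$s2a / total, pctWithin = 100 * obs$s2w / total,
       pPerm = pPerm, nPerm = nPerm,
       table = data.frame(
         source = c("among clusters", "within clusters", "total"),
         df = c(k - 1, N - k, N - 1),
         SS = c(obs$ssAmong, obs$ssWithin, obs$ssTotal),
         MS = c(obs$msAmong, obs$msWithin, NA)))
}
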