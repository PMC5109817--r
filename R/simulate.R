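#' Build a simulator configuration
#'
#' @param nAccessions number of accessions.
#' @param nMarkers number of biallelic selection markers.
#' @param K number of latent clusters.
#' @param fDiv Balding-Nichols divergence in (0,1); scalar or length-K vector.
#'   Equals the expected differentiation of each cluster from the ancestral
#'   pool.
#' @param fIs within-accession inbreeding coefficient in \[0,1\]; scalar or a
#'   vector named by species.
#' @param speciesPlan list of `list(species=, count=, weights=)` entries, where
#'   `weights` are cluster-mixture weights (length K, sum 1). `NULL` means a
#'   single species spread uniformly over clusters.
#' @param hybridFraction fraction of accessions replaced by planted F1 crosses
#'   between accessions of different clusters.
#' @param missingRate i.i.d. per-call missingness probability.
#' @param nTraitsQuant,nTraitsQual numbers of quantitative/qualitative traits.
#' @param traitEffectSd,traitNoiseSd between-cluster and within-cluster scales
#'   of quantitative traits.
#' @param nHoldoutMarkers number of multi-allelic hold-out markers.
#' @param holdoutAlleleRange (min, max) alleles per hold-out marker.
#' @param seed RNG seed; the simulation is deterministic given the config.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nAccessions, nMarkers = 48, K = 3, fDiv = 0.3,
                             fIs = 0.8, speciesPlan = NULL,
                             hybridFraction = 0, missingRate = 0.01,
                             nTraitsQuant = 0, nTraitsQual = 0,
                             traitEffectSd = 1, traitNoiseSd = 0.6,
                             nHoldoutMarkers = 0,
                             holdoutAlleleRange = c(9, 16), seed = 1) {
  if (is.null(speciesPlan)) {
    speciesPlan <- list(list(species = "sp01", count = nAccessions,
                             weights = rep(1 / K, K)))
  }
  speciesCounts <- vapply(speciesPlan, function(s) as.numeric(s$count), 0)
  names(speciesCounts) <- vapply(speciesPlan, function(s) s$species, "")
  clusterWeights <- do.call(rbind, lapply(speciesPlan, function(s) {
    w <- s$weights
    if (length(w) != K) .stopf("species '%s': weights must have length K", s$species)
    w
  }))
  rownames(clusterWeights) <- names(speciesCounts)
  if (length(fIs) > 1L && is.null(names(fIs)))
    names(fIs) <- names(speciesCounts)
  new("SimulationConfig", nAccessions = nAccessions, nMarkers = nMarkers,
      K = K, fDiv = rep_len(fDiv, K), fIs = fIs,
      speciesCounts = speciesCounts, clusterWeights = clusterWeights,
      hybridFraction = hybridFraction, missingRate = missingRate,
      nTraitsQuant = nTraitsQuant, nTraitsQual = nTraitsQual,
      traitEffectSd = traitEffectSd, traitNoiseSd = traitNoiseSd,
      nHoldoutMarkers = nHoldoutMarkers,
      holdoutAlleleRange = holdoutAlleleRange, seed = seed)
}

#' Desk-scale configuration mirroring a large structured pepper-type germplasm
#'
#' One thousand accessions stand in for a multi-thousand genebank holding:
#' 11 species of very unequal size (the dominant crop species holds 88% of
#' accessions and spans seven clusters; minor domesticated and wild species
#' occupy the remaining three), 48 biallelic markers, K = 10 latent clusters
#' whose divergences span 0.1-0.7 so that estimated differentiation covers a
#' wide range, strong selfing in the crop species (excess homozygosity),
#' a tenth of accessions planted as F1 hybrids, 17 quantitative + 15
#' qualitative cluster-correlated traits, and 3 multi-allelic hold-out
#' markers with 9-16 alleles.
#'
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
defaultPaperLikeConfig <- function(seed = 20201) {
  K <- 10
  # crop species over clusters 1-7 (unequal), minor species over 8-10
  wCrop <- c(0.18, 0.17, 0.16, 0.15, 0.13, 0.11, 0.10, 0, 0, 0)
  w8 <- c(rep(0, 7), 0.7, 0.2, 0.1)
  w9 <- c(rep(0, 7), 0.15, 0.7, 0.15)
  w10 <- c(rep(0, 9), 1)
  plan <- list(
    list(species = "sp01", count = 880, weights = wCrop),
    list(species = "sp02", count = 40, weights = w8),
    list(species = "sp03", count = 28, weights = w9),
    list(species = "sp04", count = 26, weights = w9),
    list(species = "sp05", count = 10, weights = w10),
    list(species = "sp06", count = 6, weights = w10),
    list(species = "sp07", count = 4, weights = w10),
    list(species = "sp08", count = 2, weights = w10),
    list(species = "sp09", count = 2, weights = w10),
    list(species = "sp10", count = 1, weights = w10),
    list(species = "sp11", count = 1, weights = w10))
  fIs <- c(sp01 = 0.8, sp02 = 0.7, sp03 = 0.7, sp04 = 0.7, sp05 = 0.2,
           sp06 = 0.2, sp07 = 0.1, sp08 = 0.1, sp09 = 0.1, sp10 = 0.1,
           sp11 = 0.1)
  simulationConfig(nAccessions = 1000, nMarkers = 48, K = K,
                   fDiv = seq(0.1, 0.7, length.out = K), fIs = fIs,
                   speciesPlan = plan, hybridFraction = 0.1,
                   missingRate = 0.02, nTraitsQuant = 17, nTraitsQual = 15,
                   traitEffectSd = 1, traitNoiseSd = 0.6,
                   nHoldoutMarkers = 3, holdoutAlleleRange = c(9, 16),
                   seed = seed)
}

# draw diploid biallelic calls for accessions of one cluster/inbreeding batch:
# P(hom p-allele) = p^2 + pq f, P(het) = 2pq(1-f)
.drawBiallelic <- function(p, f) {
  q <- 1 - p
  pAA <- p^2 + p * q * f
  pAB <- 2 * p * q * (1 - f)
  u <- stats::runif(length(p))
  ifelse(u < pAA, "A/A", ifelse(u < pAA + pAB, "A/B", "B/B"))
}

# draw one multi-allelic diploid call from allele frequencies with inbreeding f
.drawMultiallelic <- function(freq, labels, f) {
  a1 <- sample(labels, 1L, prob = freq)
  a2 <- if (stats::runif(1L) < f) a1 else sample(labels, 1L, prob = freq)
  paste(sort(c(a1, a2)), collapse = "/")
}

#' Simulate a structured germplasm collection with a truth record
#'
#' The generative model: each biallelic marker gets an ancestral allele
#' frequency `p ~ Uniform(0.1, 0.9)`; cluster `k`'s frequency is a
#' Balding-Nichols draw `Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)` with
#' divergence `F_k = fDiv[k]`. An accession belongs to one species (per the
#' species plan) and draws a latent cluster from its species' mixture
#' weights; its genotype at each marker follows inbreeding-adjusted
#' proportions `P(het) = 2pq(1-F_IS)`, `P(hom) = p^2 + pq F_IS` with its
#' species' `F_IS`. Planted F1 hybrids replace a random `hybridFraction` of
#' accessions and are crosses of two random non-hybrid accessions from
#' different clusters (one gamete each). Missingness is i.i.d. over calls.
#' Quantitative trait values are cluster means (`N(0, traitEffectSd^2)`) plus
#' within-cluster noise; qualitative traits are cluster-specific multinomials
#' over 3-12 classes; hold-out multi-allelic markers draw cluster frequencies
#' from a Dirichlet centred on an ancestral simplex point with the same
#' divergence scaling. Deterministic given the config (including its seed).
#'
#' @param cfg a [SimulationConfig-class].
#' @return a list with elements `collection` (a
#'   [GermplasmCollection-class]; hold-out markers, if any, sit in its
#'   `holdout` slot) and `truth` (a [TruthRecord-class]).
#' @export
simulateCollection <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nAccessions
  K <- cfg@K
  nM <- cfg@nMarkers
  accIds <- sprintf("ACC%04d", seq_len(n))
  markerIds <- sprintf("SNP%02d", seq_len(nM))

  # latent cluster frequencies per marker
  pAnc <- stats::runif(nM, 0.1, 0.9)
  clusterFreqs <- lapply(seq_len(nM), function(m) {
    vapply(seq_len(K), function(k) {
      f <- cfg@fDiv[k]
      stats::rbeta(1L, pAnc[m] * (1 - f) / f, (1 - pAnc[m]) * (1 - f) / f)
    }, 0)
  })
  names(clusterFreqs) <- markerIds

  species <- rep(names(cfg@speciesCounts), times = cfg@speciesCounts)
  names(species) <- accIds
  fIsOf <- function(sp) {
    if (length(cfg@fIs) == 1L) cfg@fIs else unname(cfg@fIs[sp])
  }
  cluster <- vapply(species, function(sp) {
    sample.int(K, 1L, prob = cfg@clusterWeights[sp, ])
  }, 0L)
  names(cluster) <- accIds

  freqMat <- do.call(rbind, clusterFreqs)  # markers x K
  calls <- matrix(NA_character_, n, nM, dimnames = list(accIds, markerIds))
  for (i in seq_len(n)) {
    calls[i, ] <- .drawBiallelic(freqMat[, cluster[i]], fIsOf(species[i]))
  }

  # hold-out multi-allelic markers
  nHold <- cfg@nHoldoutMarkers
  holdoutFreqs <- list()
  holdCalls <- NULL
  if (nHold > 0L) {
    holdIds <- sprintf("MULT%02d", seq_len(nHold))
    holdCalls <- matrix(NA_character_, n, nHold,
                        dimnames = list(accIds, holdIds))
    for (h in seq_len(nHold)) {
      nAl <- sample(seq(cfg@holdoutAlleleRange[1], cfg@holdoutAlleleRange[2]), 1L)
      labels <- sprintf("a%02d", seq_len(nAl))
      anc <- .rdirichlet(rep(1, nAl))
      fr <- t(vapply(seq_len(K), function(k) {
        f <- cfg@fDiv[k]
        .rdirichlet(anc * (1 - f) / f)
      }, numeric(nAl)))
      colnames(fr) <- labels
      holdoutFreqs[[holdIds[h]]] <- fr
      for (i in seq_len(n)) {
        holdCalls[i, h] <- .drawMultiallelic(fr[cluster[i], ], labels,
                                             fIsOf(species[i]))
      }
    }
  }

  # planted F1 hybrids: cross two non-hybrid accessions from different clusters
  nHyb <- round(cfg@hybridFraction * n)
  hybrid <- setNames(rep(FALSE, n), accIds)
  if (nHyb > 0L) {
    if (nHyb >= n - 1L) .stopf("hybridFraction leaves fewer than 2 parents")
    hybIdx <- sample.int(n, nHyb)
    hybrid[hybIdx] <- TRUE
    parentPool <- which(!hybrid)
    gamete <- function(call) sample(strsplit(call, "/", fixed = TRUE)[[1L]], 1L)
    for (i in hybIdx) {
      p1 <- sample(parentPool, 1L)
      cand <- parentPool[cluster[parentPool] != cluster[p1]]
      p2 <- if (length(cand)) {
        if (length(cand) == 1L) cand else sample(cand, 1L)
      } else sample(setdiff(parentPool, p1), 1L)
      calls[i, ] <- vapply(seq_len(nM), function(m) {
        paste(sort(c(gamete(calls[p1, m]), gamete(calls[p2, m]))),
              collapse = "/")
      }, "")
      if (!is.null(holdCalls)) {
        holdCalls[i, ] <- vapply(seq_len(nHold), function(h) {
          paste(sort(c(gamete(holdCalls[p1, h]), gamete(holdCalls[p2, h]))),
                collapse = "/")
        }, "")
      }
    }
  }

  # missingness
  if (cfg@missingRate > 0) {
    calls[stats::runif(length(calls)) < cfg@missingRate] <- NA_character_
    if (!is.null(holdCalls))
      holdCalls[stats::runif(length(holdCalls)) < cfg@missingRate] <- NA_character_
  }

  # traits
  phenotypes <- NULL
  traitMeans <- matrix(numeric(0), 0, K)
  qualProbs <- list()
  nQ <- cfg@nTraitsQuant
  nC <- cfg@nTraitsQual
  if (nQ + nC > 0L) {
    values <- list()
    traits <- data.frame(name = character(0), kind = character(0),
                         stringsAsFactors = FALSE)
    classLabels <- list()
    if (nQ > 0L) {
      # positive baselines with ~15% dispersion emulate measured crop traits
      # (lengths, weights, dates); effect/noise scales are relative to it
      base <- stats::runif(nQ, 10, 100)
      disp <- 0.15 * base
      traitMeans <- base + cfg@traitEffectSd * disp *
        matrix(stats::rnorm(nQ * K), nQ, K)
      rownames(traitMeans) <- sprintf("qt%02d", seq_len(nQ))
      for (t in seq_len(nQ)) {
        nm <- rownames(traitMeans)[t]
        values[[nm]] <- traitMeans[t, cluster] +
          stats::rnorm(n, 0, cfg@traitNoiseSd * disp[t])
        traits <- rbind(traits, data.frame(name = nm, kind = "quantitative"))
      }
    }
    if (nC > 0L) {
      for (t in seq_len(nC)) {
        nm <- sprintf("ct%02d", t)
        nCl <- sample(3:12, 1L)
        labels <- sprintf("%s_c%02d", nm, seq_len(nCl))
        probs <- t(vapply(seq_len(K), function(k) .rdirichlet(rep(1, nCl)),
                          numeric(nCl)))
        colnames(probs) <- labels
        qualProbs[[nm]] <- probs
        values[[nm]] <- vapply(seq_len(n), function(i) {
          sample(labels, 1L, prob = probs[cluster[i], ])
        }, "")
        traits <- rbind(traits, data.frame(name = nm, kind = "qualitative"))
        classLabels[[nm]] <- labels
      }
    }
    vdf <- as.data.frame(values, stringsAsFactors = FALSE, check.names = FALSE)
    rownames(vdf) <- accIds
    phenotypes <- suppressWarnings(PhenotypeTable(vdf, traits, classLabels))
  }

  passport <- PassportTable(accIds, species,
                            origin = sprintf("country%02d",
                                             1 + (cluster %% 20)),
                            source = "simulated")
  genotypes <- GenotypeMatrix(calls)
  holdout <- if (!is.null(holdCalls)) GenotypeMatrix(holdCalls)
  collection <- mergeCollection(genotypes, phenotypes, passport, holdout)

  cfNamed <- lapply(clusterFreqs, function(p) {
    m <- cbind(A = p, B = 1 - p)
    rownames(m) <- paste0("k", seq_len(K))
    m
  })
  truth <- new("TruthRecord", cluster = cluster, species = species,
               hybrid = hybrid, clusterFreqs = cfNamed,
               traitMeans = traitMeans, qualProbs = qualProbs,
               holdoutFreqs = holdoutFreqs, config = cfg)
  list(collection = collection, truth = truth)
}
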