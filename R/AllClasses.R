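#' @import methods
NULL

MISSING_ENCODINGS <- c("./.", ".|.", "NN", "", "NA", ".")

# normalize a character matrix of diploid calls: map missing encodings to NA,
# order each allele pair lexicographically ("B/A" -> "A/B")
.normalizeCalls <- function(calls) {
  v <- as.vector(calls)
  v[v %in% MISSING_ENCODINGS] <- NA_character_
  ok <- !is.na(v)
  bad <- ok & !grepl("^[^/|]+[/|][^/|]+$", v)
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(calls))
    .stopf("non-diploid call '%s' at accession '%s', marker '%s'",
           v[idx], rownames(calls)[rc[1L]], colnames(calls)[rc[2L]])
  }
  v[ok] <- gsub("|", "/", v[ok], fixed = TRUE)
  a1 <- sub("/.*$", "", v[ok])
  a2 <- sub("^.*/", "", v[ok])
  swap <- a2 < a1
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  v[ok] <- paste0(a1, "/", a2)
  matrix(v, nrow = nrow(calls), dimnames = dimnames(calls))
}

#' GenotypeMatrix: diploid calls for accessions at markers
#'
#' An accessions-by-markers matrix of diploid genotype calls. Each call is an
#' unordered pair of allele labels stored in lexicographic order (`"A/B"`), or
#' `NA` for missing. Markers may be biallelic (SNPs) or multi-allelic
#' (e.g. hold-out validation markers). Missingness is a first-class state:
#' no function in the package ever imputes a call, and every statistic
#' defines its own denominator over non-missing entries.
#'
#' @slot calls character matrix; rownames are accession ids, colnames marker ids.
#' @slot markerAlleles named list; per marker, the sorted set of observed
#'   allele labels.
#' @export
setClass("GenotypeMatrix",
  slots = c(calls = "matrix", markerAlleles = "list"))

setValidity("GenotypeMatrix", function(object) {
  calls <- object@calls
  if (!is.character(calls)) return("calls must be a character matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    return("calls must have accession rownames and marker colnames")
  dup <- rownames(calls)[duplicated(rownames(calls))]
  if (length(dup)) return(sprintf("duplicated accession id: '%s'", dup[1L]))
  dup <- colnames(calls)[duplicated(colnames(calls))]
  if (length(dup)) return(sprintf("duplicated marker id: '%s'", dup[1L]))
  if (!identical(names(object@markerAlleles), colnames(calls)))
    return("markerAlleles names must equal marker ids in order")
  for (m in colnames(calls)) {
    obs <- calls[, m]
    obs <- obs[!is.na(obs)]
    if (length(obs)) {
      al <- unique(unlist(strsplit(obs, "/", fixed = TRUE)))
      if (!all(al %in% object@markerAlleles[[m]]))
        return(sprintf("marker '%s' has calls using alleles not listed for it", m))
    }
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix of diploid calls (`"A/B"`; `"./."`, `"NN"`,
#'   `""` and `NA` all read as missing) with accession rownames and marker
#'   colnames. Pair order is irrelevant (`"B/A"` is normalized to `"A/B"`).
#' @param markerAlleles optional named list of allele labels per marker;
#'   derived from the observed calls when `NULL`.
#' @return a validated [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c("A/A", "A/B", "./.", "B/B"), nrow = 2,
#'             dimnames = list(c("acc1", "acc2"), c("m1", "m2")))
#' g <- GenotypeMatrix(m)
#' nMissing(g)
#' @export
GenotypeMatrix <- function(calls, markerAlleles = NULL) {
  calls <- .normalizeCalls(calls)
  if (is.null(markerAlleles)) {
    markerAlleles <- lapply(seq_len(ncol(calls)), function(j) {
      obs <- calls[, j]
      obs <- obs[!is.na(obs)]
      sort(unique(unlist(strsplit(obs, "/", fixed = TRUE))))
    })
    names(markerAlleles) <- colnames(calls)
  }
  new("GenotypeMatrix", calls = calls, markerAlleles = markerAlleles)
}

#' PhenotypeTable: trait scores for accessions
#'
#' Holds qualitative (categorical, with declared class labels) and
#' quantitative (numeric) trait values per accession. Qualitative values are
#' validated against their declared classes; quantitative values must be
#' finite reals. Missing values are `NA`.
#'
#' @slot values data.frame, one row per accession (rownames are accession
#'   ids), one column per trait.
#' @slot traits data.frame with columns `name` and `kind`
#'   (`"qualitative"`/`"quantitative"`).
#' @slot classLabels named list of declared class labels for qualitative traits.
#' @export
setClass("PhenotypeTable",
  slots = c(values = "data.frame", traits = "data.frame", classLabels = "list"))

setValidity("PhenotypeTable", function(object) {
  tr <- object@traits
  if (!all(c("name", "kind") %in% names(tr)))
    return("traits must have columns 'name' and 'kind'")
  if (!all(tr$kind %in% c("qualitative", "quantitative")))
    return("trait kind must be 'qualitative' or 'quantitative'")
  if (!identical(names(object@values), tr$name))
    return("value columns must match trait names in order")
  if (is.null(rownames(object@values))) return("values must have accession rownames")
  for (i in seq_len(nrow(tr))) {
    v <- object@values[[i]]
    if (tr$kind[i] == "quantitative") {
      if (!is.numeric(v)) return(sprintf("trait '%s' must be numeric", tr$name[i]))
      if (any(!is.finite(v[!is.na(v)])))
        return(sprintf("trait '%s' has non-finite values", tr$name[i]))
    } else {
      labels <- object@classLabels[[tr$name[i]]]
      if (is.null(labels)) return(sprintf("no class labels declared for '%s'", tr$name[i]))
      bad <- !is.na(v) & !(v %in% labels)
      if (any(bad)) {
        j <- which(bad)[1L]
        return(sprintf("trait '%s', accession '%s': undeclared class label '%s'",
                       tr$name[i], rownames(object@values)[j], v[j]))
      }
    }
  }
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param values data.frame of trait values, rownames = accession ids.
#' @param traits data.frame with columns `name`, `kind`.
#' @param classLabels named list of class labels for each qualitative trait.
#'   Traits with fewer than 3 or more than 12 declared classes trigger a
#'   warning (the usual working range for germplasm descriptors), not an error.
#' @return a validated [PhenotypeTable-class].
#' @export
PhenotypeTable <- function(values, traits, classLabels = list()) {
  traits$name <- as.character(traits$name)
  traits$kind <- as.character(traits$kind)
  rownames(traits) <- NULL
  obj <- new("PhenotypeTable", values = values, traits = traits,
             classLabels = classLabels)
  for (nm in traits$name[traits$kind == "qualitative"]) {
    k <- length(classLabels[[nm]])
    if (k < 3L || k > 12L)
      .warnf("qualitative trait '%s' declares %d classes (outside the usual 3-12 range)",
             nm, k)
  }
  obj
}

#' PassportTable: accession provenance
#'
#' @slot data data.frame with columns `accession`, `species`, `origin`,
#'   `source`; one row per accession.
#' @export
setClass("PassportTable", slots = c(data = "data.frame"))

setValidity("PassportTable", function(object) {
  d <- object@data
  if (!all(c("accession", "species", "origin", "source") %in% names(d)))
    return("passport data needs columns accession, species, origin, source")
  dup <- d$accession[duplicated(d$accession)]
  if (length(dup)) return(sprintf("duplicated accession id: '%s'", dup[1L]))
  if (any(is.na(d$species) | !nzchar(d$species)))
    return("species labels must be nonempty")
  TRUE
})

#' Construct a PassportTable
#'
#' @param accession character accession ids (unique).
#' @param species character species labels (nonempty).
#' @param origin country of origin; defaults to `"UNKNOWN"`.
#' @param source holding genebank or source label; defaults to `"UNKNOWN"`.
#' @return a validated [PassportTable-class].
#' @export
PassportTable <- function(accession, species, origin = "UNKNOWN",
                          source = "UNKNOWN") {
  d <- data.frame(accession = as.character(accession),
                  species = as.character(species),
                  origin = rep_len(as.character(origin), length(accession)),
                  source = rep_len(as.character(source), length(accession)),
                  stringsAsFactors = FALSE)
  new("PassportTable", data = d)
}

setClassUnion("PhenotypeTableOrNULL", c("PhenotypeTable", "NULL"))
setClassUnion("PassportTableOrNULL", c("PassportTable", "NULL"))
setClassUnion("GenotypeMatrixOrNULL", c("GenotypeMatrix", "NULL"))

#' GermplasmCollection: genotypes plus optional phenotypes, passport, hold-outs
#'
#' The top-level container the pipeline operates on. Phenotype and passport
#' accession ids must be a subset of the genotyped accessions. `holdout`
#' carries multi-allelic markers reserved for core-collection validation;
#' they are never used in selection.
#'
#' @slot genotypes a [GenotypeMatrix-class] (the selection marker panel).
#' @slot phenotypes a [PhenotypeTable-class] or `NULL`.
#' @slot passport a [PassportTable-class] or `NULL`.
#' @slot holdout a [GenotypeMatrix-class] of hold-out markers or `NULL`.
#' @export
setClass("GermplasmCollection",
  slots = c(genotypes = "GenotypeMatrix",
            phenotypes = "PhenotypeTableOrNULL",
            passport = "PassportTableOrNULL",
            holdout = "GenotypeMatrixOrNULL"))

setValidity("GermplasmCollection", function(object) {
  gid <- rownames(object@genotypes@calls)
  if (!is.null(object@phenotypes)) {
    orphan <- setdiff(rownames(object@phenotypes@values), gid)
    if (length(orphan))
      return(sprintf("phenotype accessions not genotyped: %s",
                     paste(orphan, collapse = ", ")))
  }
  if (!is.null(object@passport)) {
    orphan <- setdiff(object@passport@data$accession, gid)
    if (length(orphan))
      return(sprintf("passport accessions not genotyped: %s",
                     paste(orphan, collapse = ", ")))
  }
  if (!is.null(object@holdout)) {
    shared <- intersect(colnames(object@holdout@calls),
                        colnames(object@genotypes@calls))
    if (length(shared))
      return(sprintf("hold-out markers overlap the selection panel: %s",
                     paste(shared, collapse = ", ")))
  }
  TRUE
})

#' QCReport: result of accession-level quality control
#'
#' @slot table data.frame with columns `accession`, `hO`, `missingCount`,
#'   `hybrid`, `highMissing`, `retained`.
#' @slot retainedIds accessions passing both filters.
#' @slot hetThreshold,maxMissing the thresholds applied.
#' @export
setClass("QCReport",
  slots = c(table = "data.frame", retainedIds = "character",
            hetThreshold = "numeric", maxMissing = "numeric"))

#' ClassificationTable: class membership substrate for M-strategy selection
#'
#' Each variable (marker, qualitative trait, or Sturges-binned quantitative
#' trait) contributes a set of classes; each accession carries the classes it
#' exhibits (both alleles for a heterozygous marker call, one class per trait).
#' Classes carried by no accession are pruned.
#'
#' @slot membership logical matrix, accessions x classes.
#' @slot states data.frame with columns `variable`, `class`, `source`
#'   describing each membership column.
#' @slot variables data.frame with columns `name`, `source`, `nClasses`.
#' @slot binEdges named list of Sturges bin edges for quantitative traits.
#' @export
setClass("ClassificationTable",
  slots = c(membership = "matrix", states = "data.frame",
            variables = "data.frame", binEdges = "list"))

setValidity("ClassificationTable", function(object) {
  if (!is.logical(object@membership)) return("membership must be logical")
  if (nrow(object@states) != ncol(object@membership))
    return("states rows must match membership columns")
  if (ncol(object@membership) > 0 && any(colSums(object@membership) == 0))
    return("every class must be carried by at least one accession")
  TRUE
})

#' CoreSet: a selected core collection
#'
#' @slot strategy one of `"Gcc"`, `"Ggcc"`, `"Pcc"`, `"G+Pcc"`, `"Gg+Pcc"`,
#'   or `"custom"`.
#' @slot ids selected accession ids (selection order preserved).
#' @slot clusterOf named character vector giving, for stratified strategies,
#'   the cluster each entry was selected from (length 0 otherwise).
#' @slot classesCovered,classesTotal coverage accounting against the
#'   classification the core was selected on.
#' @slot basis `"genotype"`, `"phenotype"` or `"both"`.
#' @export
setClass("CoreSet",
  slots = c(strategy = "character", ids = "character", clusterOf = "character",
            classesCovered = "numeric", classesTotal = "numeric",
            basis = "character"))

#' EvaluationReport: core-vs-entire representativeness report
#'
#' @slot nCore,nEntire accession counts.
#' @slot continuous per-trait data.frame of mean/variance/range/CV for core
#'   and entire collection.
#' @slot aggregates list with `MD`, `VD`, `CR`, `VR` (percent scales).
#' @slot categorical list with per-variable and mean `I`, `IMax`, `J` for
#'   core and entire.
#' @slot holdout hold-out marker validation (a data.frame) or `NULL`.
#' @slot verdict `TRUE` when MD% < 20 and CR% > 80.
#' @export
setClass("EvaluationReport",
  slots = c(nCore = "numeric", nEntire = "numeric", continuous = "data.frame",
            aggregates = "list", categorical = "list", holdout = "ANY",
            verdict = "logical"))

#' SimulationConfig: parameters of the germplasm simulator
#'
#' See [simulateCollection()] for the generative model each parameter enters.
#'
#' @slot nAccessions,nMarkers,K counts.
#' @slot fDiv per-cluster Balding-Nichols divergence in (0,1); scalar or
#'   length-K vector.
#' @slot fIs within-accession inbreeding coefficient in \[0,1\]; scalar or a
#'   named per-species vector.
#' @slot speciesCounts named integer vector of accessions per species.
#' @slot clusterWeights species x K matrix of cluster-mixture weights
#'   (rows sum to 1).
#' @slot hybridFraction fraction of accessions replaced by planted F1 crosses.
#' @slot missingRate i.i.d. per-call missingness probability.
#' @slot nTraitsQuant,nTraitsQual trait counts.
#' @slot traitEffectSd,traitNoiseSd between-cluster effect and within-cluster
#'   noise scales for quantitative traits.
#' @slot nHoldoutMarkers,holdoutAlleleRange hold-out multi-allelic marker plan.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  slots = c(nAccessions = "numeric", nMarkers = "numeric", K = "numeric",
            fDiv = "numeric", fIs = "numeric", speciesCounts = "numeric",
            clusterWeights = "matrix", hybridFraction = "numeric",
            missingRate = "numeric", nTraitsQuant = "numeric",
            nTraitsQual = "numeric", traitEffectSd = "numeric",
            traitNoiseSd = "numeric", nHoldoutMarkers = "numeric",
            holdoutAlleleRange = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@nAccessions < 1 || object@nMarkers < 1 || object@K < 1)
    return("counts must be positive")
  if (object@K > object@nAccessions) return("K cannot exceed nAccessions")
  if (any(object@fDiv <= 0 | object@fDiv >= 1)) return("fDiv must be in (0,1)")
  if (any(object@fIs < 0 | object@fIs > 1)) return("fIs must be in [0,1]")
  if (object@hybridFraction < 0 || object@hybridFraction >= 1)
    return("hybridFraction must be in [0,1)")
  if (object@missingRate < 0 || object@missingRate > 1)
    return("missingRate must be in [0,1]")
  if (sum(object@speciesCounts) != object@nAccessions)
    return("speciesCounts must sum to nAccessions")
  w <- object@clusterWeights
  if (nrow(w) != length(object@speciesCounts) || ncol(w) != object@K)
    return("clusterWeights must be species x K")
  if (any(abs(rowSums(w) - 1) > 1e-8))
    return("cluster-mixture weights must sum to 1 per species")
  if (length(object@holdoutAlleleRange) != 2 ||
      object@holdoutAlleleRange[1] < 2 ||
      object@holdoutAlleleRange[2] < object@holdoutAlleleRange[1])
    return("holdoutAlleleRange must be (min, max) with min >= 2")
  TRUE
})

#' TruthRecord: latent state of a simulated collection
#'
#' @slot cluster named integer vector, latent cluster per accession.
#' @slot species named character vector.
#' @slot hybrid named logical vector flagging planted F1s.
#' @slot clusterFreqs list per marker of K x alleles frequency matrices.
#' @slot traitMeans quantitative-trait x cluster matrix of latent means.
#' @slot qualProbs list per qualitative trait of K x classes probability
#'   matrices.
#' @slot holdoutFreqs list per hold-out marker of K x alleles matrices.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("TruthRecord",
  slots = c(cluster = "integer", species = "character", hybrid = "logical",
            clusterFreqs = "list", traitMeans = "matrix", qualProbs = "list",
            holdoutFreqs = "list", config = "SimulationConfig"))
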