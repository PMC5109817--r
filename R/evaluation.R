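.coreIdVector <- function(core) {
  ids <- if (is(core, "CoreSet")) core@ids else as.character(core)
  if (length(ids) == 0L) .stopf("empty core")
  ids
}

#' Continuous-trait representativeness of a core (MD/CR/VD/VR)
#'
#' For each quantitative trait, the mean `M`, sample variance `V` (n-1
#' denominator), range `R = max - min` and coefficient of variation
#' `CV = sd/mean * 100` are computed for the core and the entire collection,
#' and aggregated over the `m` usable traits as:
#' `MD% = (100/m) sum |M_e - M_c| / |M_e|` (mean difference),
#' `VD% = (100/m) sum |V_e - V_c| / V_e` (variance difference),
#' `CR% = (100/m) sum R_c / R_e` (coincidence rate of range),
#' `VR% = (100/m) sum CV_c / CV_e` (variable rate).
#' Traits whose entire-collection denominator is zero are skipped for that
#' aggregate, with a warning. `form = "count"` instead reports MD/VD as the
#' percentage of traits with a significant core-vs-entire difference
#' (Welch t-test / F-test at 0.05), a convention used elsewhere in the
#' core-collection literature.
#'
#' @param core a [CoreSet-class] or character accession ids.
#' @param collection a [GermplasmCollection-class] with quantitative traits.
#' @param traits trait names (default: all quantitative traits).
#' @param form `"relative"` (default) or `"count"` for MD/VD.
#' @return list with `perTrait` (data.frame) and `MD`, `CR`, `VD`, `VR`.
#' @export
evaluateContinuous <- function(core, collection, traits = NULL,
                               form = c("relative", "count")) {
  form <- match.arg(form)
  coreIds <- .coreIdVector(core)
  ph <- collection@phenotypes
  if (is.null(ph)) .stopf("collection has no phenotype table")
  quant <- ph@traits$name[ph@traits$kind == "quantitative"]
  traits <- traits %||% quant
  bad <- setdiff(traits, quant)
  if (length(bad)) .stopf("not quantitative trait(s): %s", paste(bad, collapse = ", "))
  coreRows <- intersect(coreIds, rownames(ph@values))
  rows <- list()
  for (nm in traits) {
    ve <- ph@values[[nm]]
    vc <- ph@values[coreRows, nm]
    ve <- ve[!is.na(ve)]; vc <- vc[!is.na(vc)]
    if (length(ve) < 2L || length(vc) < 2L) {
      .warnf("trait '%s': fewer than 2 non-missing values; skipped", nm)
      next
    }
    rows[[nm]] <- data.frame(
      trait = nm,
      meanEntire = mean(ve), meanCore = mean(vc),
      varEntire = stats::var(ve), varCore = stats::var(vc),
      rangeEntire = diff(range(ve)), rangeCore = diff(range(vc)),
      cvEntire = 100 * stats::sd(ve) / mean(ve),
      cvCore = 100 * stats::sd(vc) / mean(vc),
      pMean = if (form == "count") stats::t.test(vc, ve)$p.value else NA_real_,
      pVar = if (form == "count") stats::var.test(vc, ve)$p.value else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) .stopf("no usable quantitative trait")
  pt <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  aggRel <- function(num, den, what) {
    ok <- is.finite(den) & den != 0
    if (!all(ok)) .warnf("%d trait(s) skipped for %s (zero denominator)",
                         sum(!ok), what)
    if (!any(ok)) return(NA_real_)
    100 * mean(num[ok] / den[ok])
  }
  if (form == "relative") {
    MD <- aggRel(abs(pt$meanEntire - pt$meanCore), abs(pt$meanEntire), "MD%")
    VD <- aggRel(abs(pt$varEntire - pt$varCore), pt$varEntire, "VD%")
  } else {
    MD <- 100 * mean(pt$pMean < 0.05)
    VD <- 100 * mean(pt$pVar < 0.05)
  }
  CR <- aggRel(pt$rangeCore, pt$rangeEntire, "CR%")
  VR <- aggRel(pt$cvCore, pt$cvEntire, "VR%")
  list(perTrait = pt, MD = MD, CR = CR, VD = VD, VR = VR)
}

# class counts of one categorical variable over a set of accessions
.categoricalCounts <- function(collection, ids) {
  out <- list()
  calls <- collection@genotypes@calls
  for (m in colnames(calls)) {
    obs <- calls[intersect(ids, rownames(calls)), m]
    obs <- obs[!is.na(obs)]
    out[[m]] <- table(obs)
  }
  ph <- collection@phenotypes
  if (!is.null(ph)) {
    qual <- ph@traits$name[ph@traits$kind == "qualitative"]
    rows <- intersect(ids, rownames(ph@values))
    for (nm in qual) {
      v <- ph@values[rows, nm]
      out[[nm]] <- table(v[!is.na(v)])
    }
  }
  out
}

#' Categorical diversity of a core versus the entire collection
#'
#' Categorical variables are the markers (classes = observed genotype
#' patterns) and the qualitative traits (classes = categories). Per
#' variable, the Shannon index `I` is computed on class frequencies in the
#' core and in the entire collection; `I_max = ln(entire-collection class
#' count)` is by default a fixed denominator used for both sets, so core and
#' entire evenness are directly comparable (`convention = "per-column"`
#' instead uses each set's own observed class count, the convention of
#' hold-out validation). Collection-level values are unweighted means over
#' variables with at least 2 entire-collection classes.
#'
#' @inheritParams evaluateContinuous
#' @param convention `"fixed"` (default) or `"per-column"` I_max denominator.
#' @return list with `perVariable` (data.frame) and `core` / `entire`
#'   summaries (`I`, `IMax`, `J`).
#' @export
evaluateCategorical <- function(core, collection,
                                convention = c("fixed", "per-column")) {
  convention <- match.arg(convention)
  coreIds <- .coreIdVector(core)
  entireCounts <- .categoricalCounts(collection, accessionIds(collection))
  coreCounts <- .categoricalCounts(collection, coreIds)
  rows <- list()
  for (nm in names(entireCounts)) {
    ce <- entireCounts[[nm]]; cc <- coreCounts[[nm]]
    if (length(ce) < 2L) next
    iE <- .shannonFromCounts(ce)
    iC <- .shannonFromCounts(cc)
    iMaxE <- log(length(ce))
    iMaxC <- if (convention == "fixed") iMaxE else log(max(length(cc), 1L))
    rows[[nm]] <- data.frame(
      variable = nm, nClassesEntire = length(ce), nClassesCore = length(cc),
      IEntire = iE, ICore = iC, IMaxEntire = iMaxE, IMaxCore = iMaxC,
      JEntire = iE / iMaxE,
      JCore = if (iMaxC > 0) iC / iMaxC else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) .stopf("no polymorphic categorical variable")
  pv <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(perVariable = pv,
       core = list(I = mean(pv$ICore), IMax = mean(pv$IMaxCore),
                   J = mean(pv$JCore, na.rm = TRUE)),
       entire = list(I = mean(pv$IEntire), IMax = mean(pv$IMaxEntire),
                     J = mean(pv$JEntire)))
}

#' Hold-out multi-allelic marker validation of a core
#'
#' Compares genetic diversity of the core and the entire collection on
#' markers that took no part in selection, using genotype patterns as
#' classes. Per marker and per set, `n` patterns, Shannon `I`,
#' `I_max = ln(n patterns observed in that set)` (per-column convention)
#' and `J' = I / I_max` are reported, with unweighted averages.
#'
#' @inheritParams evaluateContinuous
#' @param holdout a [GenotypeMatrix-class] of hold-out markers; defaults to
#'   `collection@holdout`. Its marker ids must be disjoint from the
#'   selection panel (error otherwise).
#' @return list with `perMarker` (data.frame) and `avg` (named list of
#'   averages).
#' @export
validateHoldout <- function(core, collection, holdout = NULL) {
  coreIds <- .coreIdVector(core)
  holdout <- holdout %||% collection@holdout
  if (is.null(holdout)) .stopf("no hold-out markers available")
  stopifnot(is(holdout, "GenotypeMatrix"))
  shared <- intersect(colnames(holdout@calls), markerIds(collection))
  if (length(shared))
    .stopf("hold-out markers overlap the selection panel: %s",
           paste(shared, collapse = ", "))
  rows <- list()
  for (m in colnames(holdout@calls)) {
    pe <- holdout@calls[, m]; pe <- pe[!is.na(pe)]
    pc <- holdout@calls[intersect(coreIds, rownames(holdout@calls)), m]
    pc <- pc[!is.na(pc)]
    ce <- table(pe); cc <- table(pc)
    iE <- .shannonFromCounts(ce); iC <- .shannonFromCounts(cc)
    rows[[m]] <- data.frame(
      marker = m, nPatternsEntire = length(ce), nPatternsCore = length(cc),
      IEntire = iE, ICore = iC,
      IMaxEntire = log(max(length(ce), 1L)),
      IMaxCore = log(max(length(cc), 1L)),
      JEntire = if (length(ce) > 1L) iE / log(length(ce)) else NA_real_,
      JCore = if (length(cc) > 1L) iC / log(length(cc)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  pm <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  avg <- lapply(pm[, -1], mean, na.rm = TRUE)
  list(perMarker = pm, avg = avg)
}

#' Full representativeness report for a core collection
#'
#' Assembles the continuous (MD/CR/VD/VR) and categorical (I, I_max, J')
#' comparisons, plus hold-out marker validation when hold-out markers are
#' present, and the representativeness verdict: MD% < 20 and CR% > 80.
#'
#' @inheritParams evaluateContinuous
#' @param holdout `TRUE` to validate on `collection@holdout` when present, a
#'   [GenotypeMatrix-class], or `FALSE`/`NULL` to skip.
#' @param convention I_max convention for the categorical block.
#' @return an [EvaluationReport-class].
#' @export
evaluateCore <- function(core, collection, holdout = TRUE,
                         form = c("relative", "count"),
                         convention = c("fixed", "per-column")) {
  coreIds <- .coreIdVector(core)
  nEntire <- nAccessions(collection)
  cont <- if (!is.null(collection@phenotypes) &&
              any(collection@phenotypes@traits$kind == "quantitative"))
    evaluateContinuous(coreIds, collection, form = form) else NULL
  cat_ <- evaluateCategorical(coreIds, collection, convention = convention)
  ho <- NULL
  if (isTRUE(holdout) && !is.null(collection@holdout))
    ho <- validateHoldout(coreIds, collection)
  else if (is(holdout, "GenotypeMatrix"))
    ho <- validateHoldout(coreIds, collection, holdout)
  verdict <- if (!is.null(cont)) (cont$MD < 20 && cont$CR > 80) else NA
  new("EvaluationReport", nCore = length(coreIds), nEntire = nEntire,
      continuous = if (!is.null(cont)) cont$perTrait else data.frame(),
      aggregates = if (!is.null(cont))
        list(MD = cont$MD, CR = cont$CR, VD = cont$VD, VR = cont$VR)
      else list(),
      categorical = cat_, holdout = ho, verdict = as.logical(verdict))
}

#' Cross-strategy comparison table
#'
#' One column per evaluated core plus the entire collection, rows shaped
#' like a published strategy-comparison table: entries (and percentage),
#' classes covered, MD/CR/VD/VR, and categorical I / I_max / J'. Values are
#' displayed half-up rounded to 2 decimals; underlying reports keep full
#' precision.
#'
#' @param reports named list of [EvaluationReport-class] objects (names =
#'   strategy tags).
#' @param cores optional named list of [CoreSet-class] objects matching
#'   `reports`, used for the classes-covered row.
#' @return data.frame, one row per evaluated parameter.
#' @export
strategyComparison <- function(reports, cores = NULL) {
  stopifnot(length(reports) > 0L)
  one <- function(nm) {
    r <- reports[[nm]]
    a <- r@aggregates
    c(entries = r@nCore,
      pct = roundHalfUp(100 * r@nCore / r@nEntire, 1),
      classes = if (!is.null(cores)) cores[[nm]]@classesCovered else NA,
      MD = roundHalfUp(a$MD %||% NA_real_),
      CR = roundHalfUp(a$CR %||% NA_real_),
      VD = roundHalfUp(a$VD %||% NA_real_),
      VR = roundHalfUp(a$VR %||% NA_real_),
      I = roundHalfUp(r@categorical$core$I),
      IMax = roundHalfUp(r@categorical$core$IMax),
      J = roundHalfUp(r@categorical$core$J))
  }
  out <- vapply(names(reports), one, numeric(10))
  r1 <- reports[[1L]]
  entire <- c(entries = r1@nEntire, pct = 100, classes = NA, MD = NA,
              CR = NA, VD = NA, VR = NA,
              I = roundHalfUp(r1@categorical$entire$I),
              IMax = roundHalfUp(r1@categorical$entire$IMax),
              J = roundHalfUp(r1@categorical$entire$J))
  data.frame(parameter = rownames(cbind(out, entire)), out,
             entire = entire, check.names = FALSE, row.names = NULL)
}
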