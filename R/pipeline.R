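.KNOWN_KEYS <- list(
  top = c("seed", "output_dir", "simulation", "input", "qc", "clustering",
          "strategies", "evaluation", "log_level"),
  simulation = c("n_accessions", "n_markers", "k", "f_div", "f_is",
                 "hybrid_fraction", "missing_rate", "n_traits_quant",
                 "n_traits_qual", "trait_effect_sd", "trait_noise_sd",
                 "n_holdout_markers", "holdout_allele_range", "seed",
                 "paper_like"),
  input = c("dir"),
  qc = c("het_threshold", "max_missing"),
  clustering = c("method", "k"),
  evaluation = c("md_vd_form", "imax_convention"))

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    .stopf("unknown config key at %s: '%s'", where, unknown[1L])
}

#' Validate a pipeline configuration
#'
#' Schema-checked, fail-closed: unknown keys are an error naming the key.
#' Exactly one of `simulation` or `input` must be present. A missing seed is
#' drawn at random and recorded in the returned config (and later in the run
#' manifest).
#'
#' @param config path to a YAML file or an already-parsed list.
#' @return the validated config list (class `"PipelineConfig"`), with
#'   defaults filled in.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stopf("config must be a YAML mapping")
  .checkKeys(config, .KNOWN_KEYS$top, "top level")
  hasSim <- !is.null(config$simulation)
  hasInput <- !is.null(config$input)
  if (hasSim == hasInput)
    .stopf("config must have exactly one of 'simulation' or 'input'")
  if (hasSim) .checkKeys(config$simulation, .KNOWN_KEYS$simulation, "simulation")
  if (hasInput) {
    .checkKeys(config$input, .KNOWN_KEYS$input, "input")
    if (is.null(config$input$dir)) .stopf("input.dir is required")
    if (!dir.exists(config$input$dir))
      .stopf("input.dir does not exist: %s", config$input$dir)
  }
  .checkKeys(config$qc %||% list(), .KNOWN_KEYS$qc, "qc")
  .checkKeys(config$clustering %||% list(), .KNOWN_KEYS$clustering, "clustering")
  .checkKeys(config$evaluation %||% list(), .KNOWN_KEYS$evaluation, "evaluation")
  config$qc <- list(het_threshold = config$qc$het_threshold %||% 0.3,
                    max_missing = config$qc$max_missing %||% 7)
  config$clustering <- list(method = config$clustering$method %||% "upgma",
                            k = config$clustering$k %||% 5)
  if (!identical(config$clustering$method, "upgma"))
    .stopf("clustering.method must be 'upgma' (cluster extraction needs a rooted tree)")
  config$evaluation <- list(
    md_vd_form = config$evaluation$md_vd_form %||% "relative",
    imax_convention = config$evaluation$imax_convention %||% "fixed")
  config$strategies <- config$strategies %||%
    c("Gcc", "Ggcc", "Pcc", "G+Pcc", "Gg+Pcc")
  bad <- setdiff(config$strategies, c("Gcc", "Ggcc", "Pcc", "G+Pcc", "Gg+Pcc"))
  if (length(bad)) .stopf("unknown strategy: '%s'", bad[1L])
  if (is.null(config$seed)) {
    config$seed <- sample.int(.Machine$integer.max, 1L)
    message(sprintf("no seed in config; drew and recorded seed %d", config$seed))
  }
  config$output_dir <- config$output_dir %||% "germcore-run"
  class(config) <- c("PipelineConfig", class(config))
  config
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # where results land is not part of the analysis
  cfg$log_level <- NULL
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.writeCsvHash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.simConfigFromList <- function(sim, fallbackSeed) {
  if (isTRUE(sim$paper_like)) {
    cfg <- defaultPaperLikeConfig(seed = sim$seed %||% fallbackSeed)
    return(cfg)
  }
  simulationConfig(
    nAccessions = sim$n_accessions %||% .stopf("simulation.n_accessions required"),
    nMarkers = sim$n_markers %||% 48,
    K = sim$k %||% 3,
    fDiv = sim$f_div %||% 0.3,
    fIs = sim$f_is %||% 0.8,
    hybridFraction = sim$hybrid_fraction %||% 0,
    missingRate = sim$missing_rate %||% 0.01,
    nTraitsQuant = sim$n_traits_quant %||% 0,
    nTraitsQual = sim$n_traits_qual %||% 0,
    traitEffectSd = sim$trait_effect_sd %||% 1,
    traitNoiseSd = sim$trait_noise_sd %||% 0.6,
    nHoldoutMarkers = sim$n_holdout_markers %||% 0,
    holdoutAlleleRange = unlist(sim$holdout_allele_range %||% c(9, 16)),
    seed = sim$seed %||% fallbackSeed)
}

#' Run the full core-collection pipeline
#'
#' Orchestrates simulate-or-load, QC, diversity reporting, Manhattan
#' distances with UPGMA and NJ trees, tree-cut clustering, PCoA, core
#' selection under the requested strategies, and per-core evaluation with a
#' cross-strategy comparison table. All stochastic stages derive from the
#' config seed, so a rerun with the same config is bit-identical. Reports
#' are csv/json/Newick files in the output directory; each csv report opens
#' with a `# config_hash:` comment line and the run manifest records the
#' config echo, hash, seed and package version.
#'
#' @param config a config path/list accepted by [validateConfig()].
#' @param outputDir overrides the config's `output_dir`.
#' @return invisibly, a list with the collection, QC report, cluster labels,
#'   cores, evaluation reports, comparison table and output paths.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validateConfig(config)
  out <- outputDir %||% cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- obtain collection -------------------------------------------------
  truth <- NULL
  collection <- stage("input", {
    if (!is.null(cfg$simulation)) {
      sim <- simulateCollection(.simConfigFromList(cfg$simulation, cfg$seed))
      truth <- sim$truth
      writeCollection(sim$collection, file.path(out, "collection"))
      jsonlite::write_json(
        list(config_hash = hash,
             cluster = as.list(sim$truth@cluster),
             hybrid = as.list(sim$truth@hybrid),
             species = as.list(sim$truth@species)),
        file.path(out, "truth.json"), auto_unbox = TRUE)
      sim$collection
    } else {
      readCollection(cfg$input$dir)
    }
  })

  # --- qc ---------------------------------------------------------------
  qc <- stage("qc", applyQC(collection@genotypes,
                            hetThreshold = cfg$qc$het_threshold,
                            maxMissing = cfg$qc$max_missing))
  .writeCsvHash(qc@table, file.path(out, "qc_report.csv"), hash)
  retained <- collection[retainedIds(qc), ]

  # --- diversity --------------------------------------------------------
  stage("diversity", {
    grouping <- if (!is.null(retained@passport)) "species" else "total"
    div <- groupDiversity(retained, grouping)
    .writeCsvHash(div, file.path(out, "diversity_by_species.csv"), hash)
  })

  # --- distance, trees, clusters, pcoa ---------------------------------
  clusters <- stage("clustering", {
    D <- manhattanDissimilarity(retained@genotypes)
    upgma <- upgmaTree(D)
    exportNewick(upgma, file.path(out, "upgma.nwk"))
    if (nAccessions(retained) >= 3L)
      exportNewick(njTree(D), file.path(out, "nj.nwk"))
    cl <- cutTree(upgma, k = cfg$clustering$k)
    .writeCsvHash(data.frame(accession = names(cl), cluster = unname(cl)),
                  file.path(out, "clusters.csv"), hash)
    .writeCsvHash(fstPerCluster(retained@genotypes, cl),
                  file.path(out, "diversity_by_cluster.csv"), hash)
    if (all(table(cl) >= 2L)) {
      am <- amova(D, cl, nPerm = 199, seed = cfg$seed)
      jsonlite::write_json(
        c(list(config_hash = hash), am[c("sigma2Among", "sigma2Within", "phiST",
                                         "pctAmong", "pctWithin", "pPerm",
                                         "nPerm")]),
        file.path(out, "amova.json"), auto_unbox = TRUE, digits = NA)
    } else {
      .warnf("singleton cluster at k=%d; AMOVA skipped", cfg$clustering$k)
    }
    pc <- runPcoa(D, nAxes = 2)
    .writeCsvHash(data.frame(accession = rownames(pc$coordinates),
                             pc$coordinates,
                             pctAxis1 = pc$pctVariance[1L],
                             pctAxis2 = pc$pctVariance[2L]),
                  file.path(out, "pcoa.csv"), hash)
    cl
  })

  # --- selection + evaluation ------------------------------------------
  cores <- list()
  reports <- list()
  for (s in cfg$strategies) {
    cores[[s]] <- stage(paste0("select:", s),
                        runStrategy(retained, s, clusters = clusters))
    writeCoreSet(cores[[s]],
                 file.path(out, paste0("core_", gsub("[+]", "p", s), ".csv")))
    reports[[s]] <- stage(paste0("evaluate:", s),
      evaluateCore(cores[[s]], retained,
                   form = cfg$evaluation$md_vd_form,
                   convention = cfg$evaluation$imax_convention))
  }
  comparison <- stage("comparison", strategyComparison(reports, cores))
  .writeCsvHash(comparison, file.path(out, "strategy_comparison.csv"), hash)

  manifest <- list(package = "germCore",
                   version = as.character(utils::packageVersion("germCore")),
                   seed = cfg$seed, config_hash = hash,
                   config = unclass(cfg),
                   files = list.files(out, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(collection = collection, truth = truth, qc = qc,
                 clusters = clusters, cores = cores, reports = reports,
                 comparison = comparison, outputDir = out,
                 configHash = hash))
}
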