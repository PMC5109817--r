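#' Read a genotype matrix from delimited text or VCF
#'
#' The `matrix-csv` dialect is a UTF-8 comma-delimited table whose first
#' header cell is `accession`, remaining header cells are marker ids, and
#' cells are diploid calls like `"A/A"`, `"A/B"`; `"./."`, `"NN"` and empty
#' cells are read as missing. The `vcf` dialect reads the GT field of diploid
#' records (requires the vcfR package): REF maps to allele `"R"`, ALT alleles
#' to `"A"` (`"A2"`, ... for additional ALTs), and `contig:pos` becomes the
#' marker id (coordinates are kept as opaque ids; no coordinate arithmetic
#' happens downstream).
#'
#' @param path file path.
#' @param dialect `"matrix-csv"` (default) or `"vcf"`.
#' @return a validated [GenotypeMatrix-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, dialect = c("matrix-csv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("genotype file not found: %s", path)
  if (dialect == "vcf") return(.readGenotypesVcf(path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L || tolower(names(df)[1L]) != "accession")
    .stopf("matrix-csv must start with an 'accession' column: %s", path)
  acc <- df[[1L]]
  dup <- acc[duplicated(acc)]
  if (length(dup)) .stopf("duplicated accession id in %s: '%s'", path, dup[1L])
  markers <- names(df)[-1L]
  dup <- markers[duplicated(markers)]
  if (length(dup)) .stopf("duplicated marker id in %s: '%s'", path, dup[1L])
  calls <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(calls) <- list(acc, markers)
  GenotypeMatrix(calls)
}

.readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stopf("the vcf dialect requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  alt <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  out <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), ids))
  for (i in seq_len(nrow(gt))) {
    labels <- c("R", if (length(alt[[i]]) > 1L)
      paste0("A", seq_along(alt[[i]])) else "A"[length(alt[[i]]) == 1L])
    g <- gt[i, ]
    miss <- is.na(g) | g %in% c("./.", ".|.", ".")
    codes <- strsplit(g[!miss], "[/|]")
    bad <- lengths(codes) != 2L
    if (any(bad))
      .stopf("non-diploid GT at %s, sample '%s'", ids[i],
             names(g[!miss])[which(bad)[1L]])
    out[!miss, i] <- vapply(codes, function(cd) {
      k <- as.integer(cd) + 1L
      if (any(k > length(labels))) .stopf("allele index out of range at %s", ids[i])
      paste(sort(labels[k]), collapse = "/")
    }, character(1L))
  }
  GenotypeMatrix(out)
}

#' Write a genotype matrix as matrix-csv
#'
#' Rows and columns are written in the object's order; missing calls are
#' written as `"./."`; allele pairs are already in lexicographic order, so
#' `readGenotypes(writeGenotypes(g))` round-trips calls, ids and missingness
#' exactly.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path) {
  stopifnot(is(g, "GenotypeMatrix"))
  calls <- g@calls
  calls[is.na(calls)] <- "./."
  df <- data.frame(accession = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) .stopf("cannot write genotypes to %s: %s",
                                      path, conditionMessage(e)))
  invisible(path)
}

#' Read a phenotype table against a declared trait schema
#'
#' @param path csv with first column `accession`, one column per trait.
#' @param schema either a path to a schema json file or a list of trait
#'   descriptors `list(name=, kind=, classes=)` (`classes` required for
#'   qualitative traits). Every trait column in the file must be declared.
#' @return a validated [PhenotypeTable-class].
#' @export
readPhenotypes <- function(path, schema) {
  if (!file.exists(path)) .stopf("phenotype file not found: %s", path)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  names(schema) <- vapply(schema, `[[`, "", "name")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("NA", ""))
  if (tolower(names(df)[1L]) != "accession")
    .stopf("phenotype csv must start with an 'accession' column")
  acc <- df[[1L]]
  traitNames <- names(df)[-1L]
  undeclared <- setdiff(traitNames, names(schema))
  if (length(undeclared))
    .stopf("trait column(s) not declared in schema: %s",
           paste(undeclared, collapse = ", "))
  traits <- data.frame(
    name = traitNames,
    kind = vapply(schema[traitNames], `[[`, "", "kind"),
    stringsAsFactors = FALSE)
  classLabels <- lapply(schema[traitNames], function(s) s$classes)
  classLabels <- classLabels[!vapply(classLabels, is.null, TRUE)]
  values <- df[, -1L, drop = FALSE]
  rownames(values) <- acc
  for (i in seq_along(traitNames)) {
    nm <- traitNames[i]
    if (traits$kind[i] == "quantitative") {
      suppressWarnings(num <- as.numeric(values[[nm]]))
      bad <- !is.na(values[[nm]]) & is.na(num)
      if (any(bad))
        .stopf("trait '%s', accession '%s': non-numeric value '%s'",
               nm, acc[which(bad)[1L]], values[[nm]][which(bad)[1L]])
      values[[nm]] <- num
    } else {
      bad <- !is.na(values[[nm]]) & !(values[[nm]] %in% classLabels[[nm]])
      if (any(bad))
        .stopf("trait '%s', accession '%s': undeclared class label '%s'",
               nm, acc[which(bad)[1L]], values[[nm]][which(bad)[1L]])
    }
  }
  PhenotypeTable(values, traits, classLabels)
}

#' Write a phenotype table and its schema
#'
#' @param p a [PhenotypeTable-class].
#' @param path output csv path.
#' @param schemaPath optional path for the trait schema json.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(p, path, schemaPath = NULL) {
  stopifnot(is(p, "PhenotypeTable"))
  df <- data.frame(accession = rownames(p@values), p@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(schemaPath)) {
    schema <- lapply(seq_len(nrow(p@traits)), function(i) {
      s <- list(name = p@traits$name[i], kind = p@traits$kind[i])
      if (s$kind == "qualitative") s$classes <- p@classLabels[[s$name]]
      s
    })
    jsonlite::write_json(schema, schemaPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read/write a passport table
#'
#' @param path csv with columns `accession`, `species` and optionally
#'   `origin`, `source` (missing entries become `"UNKNOWN"`).
#' @return a validated [PassportTable-class].
#' @export
readPassport <- function(path) {
  if (!file.exists(path)) .stopf("passport file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("NA", ""))
  if (!all(c("accession", "species") %in% names(df)))
    .stopf("passport csv needs 'accession' and 'species' columns")
  origin <- df$origin %||% "UNKNOWN"
  source <- df$source %||% "UNKNOWN"
  origin[is.na(origin)] <- "UNKNOWN"
  source[is.na(source)] <- "UNKNOWN"
  PassportTable(df$accession, df$species, origin, source)
}

#' @rdname readPassport
#' @param pp a [PassportTable-class].
#' @export
writePassport <- function(pp, path) {
  stopifnot(is(pp, "PassportTable"))
  utils::write.csv(pp@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a GermplasmCollection
#'
#' Joins genotypes with optional phenotype, passport and hold-out marker
#' tables, checking id consistency: phenotype/passport accessions must all be
#' genotyped (orphans are an error, enumerated in the message). A phenotype
#' table with no traits or no rows is treated as absent.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param phenotypes a [PhenotypeTable-class] or `NULL`.
#' @param passport a [PassportTable-class] or `NULL`.
#' @param holdout a [GenotypeMatrix-class] of validation markers or `NULL`;
#'   its marker ids must be disjoint from the selection panel.
#' @return a validated [GermplasmCollection-class].
#' @export
mergeCollection <- function(genotypes, phenotypes = NULL, passport = NULL,
                            holdout = NULL) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  if (!is.null(phenotypes) &&
      (nrow(phenotypes@values) == 0L || ncol(phenotypes@values) == 0L))
    phenotypes <- NULL
  new("GermplasmCollection", genotypes = genotypes, phenotypes = phenotypes,
      passport = passport, holdout = holdout)
}

#' Write or read a whole collection as a directory of delimited files
#'
#' Emits `genotypes.csv`, and when present `phenotypes.csv` +
#' `phenotype_schema.json`, `passport.csv`, `holdout_genotypes.csv`.
#'
#' @param collection a [GermplasmCollection-class].
#' @param dir output directory (created if needed).
#' @return `dir` (for `writeCollection`) or a rebuilt collection
#'   (for `readCollection`), invisibly/visibly.
#' @export
writeCollection <- function(collection, dir) {
  stopifnot(is(collection, "GermplasmCollection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypes(collection@genotypes, file.path(dir, "genotypes.csv"))
  if (!is.null(collection@phenotypes))
    writePhenotypes(collection@phenotypes, file.path(dir, "phenotypes.csv"),
                    file.path(dir, "phenotype_schema.json"))
  if (!is.null(collection@passport))
    writePassport(collection@passport, file.path(dir, "passport.csv"))
  if (!is.null(collection@holdout))
    writeGenotypes(collection@holdout, file.path(dir, "holdout_genotypes.csv"))
  invisible(dir)
}

#' @rdname writeCollection
#' @export
readCollection <- function(dir) {
  g <- readGenotypes(file.path(dir, "genotypes.csv"))
  ph <- if (file.exists(file.path(dir, "phenotypes.csv")))
    readPhenotypes(file.path(dir, "phenotypes.csv"),
                   file.path(dir, "phenotype_schema.json"))
  pp <- if (file.exists(file.path(dir, "passport.csv")))
    readPassport(file.path(dir, "passport.csv"))
  ho <- if (file.exists(file.path(dir, "holdout_genotypes.csv")))
    readGenotypes(file.path(dir, "holdout_genotypes.csv"))
  mergeCollection(g, ph, pp, ho)
}
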