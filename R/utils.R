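# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# split a vector of normalized diploid calls "x/y" into its two allele vectors;
# NA calls yield NA in both components
.callAlleles <- function(calls) {
  a1 <- sub("/.*$", "", calls)
  a2 <- sub("^.*/", "", calls)
  a1[is.na(calls)] <- NA_character_
  a2[is.na(calls)] <- NA_character_
  list(a1 = a1, a2 = a2)
}

.isHet <- function(calls) {
  al <- .callAlleles(calls)
  ifelse(is.na(calls), NA, al$a1 != al$a2)
}

# Shannon entropy (natural log) from a vector of counts or frequencies
.shannonFromCounts <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  f <- counts / sum(counts)
  -sum(f * log(f))
}

# one Dirichlet draw
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[sample.int(length(x), 1L)] <- 1
  x / sum(x)
}

#' Round half-up to a fixed number of decimals
#'
#' The display convention of the report tables (base `round()` rounds half
#' to even). Internal report values keep full precision; rounding is applied
#' only when tables are rendered.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
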