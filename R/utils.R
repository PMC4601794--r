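## Internal helpers shared across modules.

## Validity flags attached to per-SNP accuracy records.  A statistic that
## cannot be computed is reported as NA together with the flag naming why.
FLAG_MONOMORPHIC <- "MONOMORPHIC"
FLAG_DEGENERATE_VARIANCE <- "DEGENERATE_VARIANCE"
FLAG_THETA_BOUNDARY <- "THETA_BOUNDARY"
FLAG_EMPTY_LD_PANEL <- "EMPTY_LD_PANEL"

## Denominators (1 - Pc, variance terms, theta * (1 - theta)) are compared
## against this tolerance before dividing, so near-degenerate tables yield a
## flagged NA instead of a floating-point sign flip.
DENOM_TOL <- 1e-12

## Probability rows may be rounded to few decimals by imputation programs;
## rows whose sum is within this tolerance of 1 are renormalized, rows
## further out are rejected.
ROW_SUM_TOL <- 1e-4

#' @importFrom methods is new validObject slot show
#' @importFrom stats rbinom rgamma runif sd setNames
#' @importFrom utils write.table
NULL

.assertProbMatrix <- function(probs, what = "probs") {
  if (!is.matrix(probs) || !is.numeric(probs) || ncol(probs) != 3L)
    stop(what, " must be a numeric matrix with 3 columns (AA, AB, BB)")
  if (anyNA(probs) || any(probs < -ROW_SUM_TOL) || any(probs > 1 + ROW_SUM_TOL))
    stop(what, " entries must lie in [0, 1]")
  invisible(TRUE)
}

## Renormalize probability rows summing to 1 within ROW_SUM_TOL; reject others.
normalizeProbRows <- function(probs, tol = ROW_SUM_TOL) {
  .assertProbMatrix(probs)
  s <- rowSums(probs)
  if (any(abs(s - 1) > tol))
    stop("probability row sum outside [1 - ", tol, ", 1 + ", tol, "]: ",
         format(s[which.max(abs(s - 1))], digits = 10))
  probs <- pmin(pmax(probs, 0), 1)
  sweep(probs, 1L, rowSums(probs), "/")
}

.assertCalls <- function(calls, what = "calls") {
  if (!is.numeric(calls))
    stop(what, " must be numeric genotype codes in {0, 1, 2} (NA = missing)")
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok))
    stop(what, " contains values outside {0, 1, 2, NA}")
  invisible(TRUE)
}

## Genotype class counts (AA, AB, BB) among non-missing calls.
classCounts <- function(calls) {
  .assertCalls(calls)
  tabulate(calls[!is.na(calls)] + 1L, nbins = 3L)
}

.collapseFlags <- function(flags) {
  if (length(flags) == 0L) "" else paste(sort(unique(flags)), collapse = ";")
}

## A/T and C/G allele pairs cannot be disambiguated from a strand flip.
.isAmbiguousPair <- function(a, b) {
  p <- paste0(toupper(a), toupper(b))
  p %in% c("AT", "TA", "CG", "GC")
}
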