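## Per-SNP imputation accuracy statistics.
##
## All statistics are computed from an N x 3 matrix of imputed genotype
## probabilities (columns AA, AB, BB; B = coded allele) and, where truth is
## needed, a length-N vector of true calls in {0, 1, 2, NA}.  Individuals
## with missing truth are excluded pairwise; nothing is imputed for them.

#' Build the imputed-versus-actual probability contingency table
#'
#' Sums imputed probability mass into a 3 x 3 table: cell (i, j) accumulates
#' the class-i probability of every individual whose actual genotype class is
#' j.  Individuals with missing truth are excluded entirely, so column totals
#' equal the actual class counts and the grand total is the number of
#' individuals used.
#'
#' @param probs N x 3 matrix of imputed genotype probabilities (rows
#'   renormalized under the row-sum tolerance of 1e-4).
#' @param truth length-N vector of true calls in \{0, 1, 2, NA\}.
#' @return A \linkS4class{ProbabilityTable}.
#' @examples
#' probabilityTable(rbind(c(1, 0, 0), c(0, 1, 0)), c(0, 1))
#' @export
probabilityTable <- function(probs, truth) {
  probs <- normalizeProbRows(probs)
  .assertCalls(truth, "truth")
  if (nrow(probs) != length(truth))
    stop("probs and truth are not aligned: ", nrow(probs), " rows vs ",
         length(truth), " calls")
  keep <- !is.na(truth)
  if (!any(keep))
    stop("no non-missing truth calls")
  probs <- probs[keep, , drop = FALSE]
  truth <- truth[keep]
  cells <- matrix(0, 3L, 3L)
  for (j in 0:2) {
    rows <- truth == j
    if (any(rows))
      cells[, j + 1L] <- colSums(probs[rows, , drop = FALSE])
  }
  new("ProbabilityTable", cells = cells,
      classCounts = tabulate(truth + 1L, nbins = 3L),
      nUsed = sum(keep))
}

#' Concordance rate
#'
#' The probability-weighted proportion of agreement: the summed diagonal mass
#' of the contingency table divided by the number of individuals.
#'
#' @param table a \linkS4class{ProbabilityTable}.
#' @return Proportion in [0, 1].
#' @export
concordanceRate <- function(table) {
  stopifnot(is(table, "ProbabilityTable"))
  if (table@nUsed == 0L) stop("empty table")
  sum(diag(table@cells)) / table@nUsed
}

#' Chance agreement
#'
#' Agreement expected from the table margins alone: the sum over classes of
#' (actual class count) x (imputed row total), divided by N squared.
#'
#' @inheritParams concordanceRate
#' @return Proportion in [0, 1].
#' @export
chanceAgreement <- function(table) {
  stopifnot(is(table, "ProbabilityTable"))
  if (table@nUsed == 0L) stop("empty table")
  sum(table@classCounts * rowSums(table@cells)) / table@nUsed^2
}

#' Imputation Quality Score
#'
#' Cohen's-kappa-style chance-corrected agreement,
#' (Po - Pc) / (1 - Pc), on the probability contingency table.  A score of 1
#' means the imputed mass sits exactly on the true genotypes; 0 means no
#' better than chance; negative means worse than chance.  When the truth is
#' effectively single-class (1 - Pc below tolerance) the score is undefined
#' and \code{NA} is returned with a \code{MONOMORPHIC} flag attribute.
#'
#' IQS never exceeds the concordance rate: Po*Pc <= Pc gives
#' Po - Pc <= Po - Po*Pc, hence (Po - Pc)/(1 - Pc) <= Po.
#'
#' @inheritParams concordanceRate
#' @return Score <= 1 (possibly negative), or \code{NA} when undefined.
#' @export
iqs <- function(table) {
  po <- concordanceRate(table)
  pc <- chanceAgreement(table)
  if (1 - pc < DENOM_TOL) {
    out <- NA_real_
    attr(out, "flag") <- FLAG_MONOMORPHIC
    return(out)
  }
  (po - pc) / (1 - pc)
}

#' Dosage summaries of a probability matrix
#'
#' Per-individual quantities used by the program-reported accuracy measures:
#' expected coded-allele dosage \code{e = p_AB + 2 p_BB}, second moment
#' \code{f = p_AB + 4 p_BB} (so \code{f - e^2} is the per-individual dosage
#' variance), best-guess genotype \code{z} (the class with the highest
#' posterior probability, lowest index on ties), and the sample coded-allele
#' frequency \code{thetaHat = mean(e) / 2}.
#'
#' @param probs N x 3 matrix of imputed genotype probabilities.
#' @return List with elements \code{e}, \code{f}, \code{z},
#'   \code{thetaHat}.
#' @examples
#' dosageSummaries(rbind(c(0.2, 0.5, 0.3)))  # e = 1.1, f = 1.7, z = 1
#' @export
dosageSummaries <- function(probs) {
  probs <- normalizeProbRows(probs)
  e <- probs[, 2L] + 2 * probs[, 3L]
  f <- probs[, 2L] + 4 * probs[, 3L]
  z <- max.col(probs, ties.method = "first") - 1L
  list(e = e, f = f, z = z, thetaHat = mean(e) / 2)
}

#' Least-squares components of the dosage regression
#'
#' Sums of squares and the slope of the least-squares regression of true on
#' imputed dosage, computed on pairwise-complete observations.  Exposed so
#' that the squared-correlation decomposition (SSE <= SSyy, beta = SSxy/SSxx)
#' is directly testable.
#'
#' @param x imputed dosage vector.
#' @param y true dosage vector (NA allowed; pairs deleted).
#' @return List with \code{SSxx}, \code{SSyy}, \code{SSxy}, \code{SSE},
#'   \code{betaHat}, \code{nUsed}.
#' @export
correlationComponents <- function(x, y) {
  if (length(x) != length(y)) stop("x and y are not aligned")
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 2L) stop("fewer than 2 pairwise-complete observations")
  x <- x[keep]; y <- y[keep]
  SSxx <- sum((x - mean(x))^2)
  SSyy <- sum((y - mean(y))^2)
  SSxy <- sum((x - mean(x)) * (y - mean(y)))
  betaHat <- if (SSxx < DENOM_TOL) NA_real_ else SSxy / SSxx
  SSE <- if (is.na(betaHat)) NA_real_ else SSyy - betaHat * SSxy
  list(SSxx = SSxx, SSyy = SSyy, SSxy = SSxy, SSE = SSE,
       betaHat = betaHat, nUsed = sum(keep))
}

#' Squared dosage correlation
#'
#' The square of the Pearson correlation between imputed and true dosage,
#' computed as \code{1 - SSE/SSyy} from the least-squares decomposition.
#' Undefined (NA with \code{DEGENERATE_VARIANCE} flag) when either dosage
#' vector has (near-)zero variance.
#'
#' @inheritParams correlationComponents
#' @return R-squared in [0, 1], or \code{NA} when undefined.
#' @export
squaredCorrelation <- function(x, y) {
  cc <- correlationComponents(x, y)
  if (cc$SSxx < DENOM_TOL || cc$SSyy < DENOM_TOL) {
    out <- NA_real_
    attr(out, "flag") <- FLAG_DEGENERATE_VARIANCE
    return(out)
  }
  min(max(1 - cc$SSE / cc$SSyy, 0), 1)
}

#' Allelic R-squared in the BEAGLE style
#'
#' Approximates the squared correlation between the best-guess genotype
#' \code{z} and the unobserved true dosage, computable from the probability
#' matrix alone: the squared covariance of \code{z} and the expected dosage
#' \code{e}, divided by the product of (i) \code{sum(f) - (sum(e))^2/N},
#' the expected-dosage variance term inflated by per-individual dosage
#' uncertainty, and (ii) the variance of \code{z}.  Undefined when either
#' variance term is (near-)zero, e.g. when every row has the same best
#' guess.  Tiny negative numerators from floating point are clipped to 0 and
#' the result is clipped into [0, 1].
#'
#' @param probs N x 3 matrix of imputed genotype probabilities.
#' @return Score in [0, 1], or \code{NA} when undefined.
#' @export
beagleR2 <- function(probs) {
  probs <- normalizeProbRows(probs)
  n <- nrow(probs)
  if (n < 2L) stop("need at least 2 individuals")
  d <- dosageSummaries(probs)
  num <- (sum(d$z * d$e) - sum(d$z) * sum(d$e) / n)^2
  denE <- sum(d$f) - sum(d$e)^2 / n
  denZ <- sum(d$z^2) - sum(d$z)^2 / n
  if (denE < DENOM_TOL || denZ < DENOM_TOL) {
    out <- NA_real_
    attr(out, "flag") <- FLAG_DEGENERATE_VARIANCE
    return(out)
  }
  min(max(num / (denE * denZ), 0), 1)
}

#' IMPUTE2 INFO measure
#'
#' \code{1 - sum(f - e^2) / (2 N thetaHat (1 - thetaHat))}: one minus the
#' ratio of total imputed dosage uncertainty to the binomial dosage variance
#' at the sample allele frequency.  At most 1 (attained when every row is
#' degenerate) and possibly negative.  Undefined (NA, \code{THETA_BOUNDARY}
#' flag) when the sample allele frequency is at 0 or 1.
#'
#' @param probs N x 3 matrix of imputed genotype probabilities.
#' @return Score <= 1, or \code{NA} when undefined.
#' @export
impute2Info <- function(probs) {
  probs <- normalizeProbRows(probs)
  d <- dosageSummaries(probs)
  th <- d$thetaHat
  if (th * (1 - th) < DENOM_TOL) {
    out <- NA_real_
    attr(out, "flag") <- FLAG_THETA_BOUNDARY
    return(out)
  }
  1 - sum(d$f - d$e^2) / (2 * nrow(probs) * th * (1 - th))
}

#' Assess one SNP
#'
#' Computes every accuracy statistic for one SNP on the pairwise-complete
#' individuals, together with the truth-based minor allele frequency and
#' validity flags.  Statistics that are undefined on this input (monomorphic
#' truth, degenerate variance, boundary allele frequency) are reported as
#' \code{NA} with the corresponding flag, never fabricated.
#'
#' @param probs N x 3 matrix of imputed genotype probabilities.
#' @param truth length-N vector of true calls in \{0, 1, 2, NA\}.
#' @param snpId identifier copied into the record.
#' @return One-row data.frame: \code{snp_id}, \code{n_used}, \code{maf},
#'   \code{concordance}, \code{chance_agreement}, \code{iqs}, \code{r2},
#'   \code{beagle_r2}, \code{impute2_info}, \code{flags}
#'   (semicolon-separated).
#' @export
assessSnp <- function(probs, truth, snpId = "snp") {
  probs <- normalizeProbRows(probs)
  .assertCalls(truth, "truth")
  if (nrow(probs) != length(truth))
    stop("probs and truth are not aligned")
  keep <- !is.na(truth)
  if (!any(keep)) stop("no non-missing truth calls")
  probs <- probs[keep, , drop = FALSE]
  truth <- truth[keep]

  flags <- character(0)
  cc <- classCounts(truth)
  if (sum(cc > 0L) < 2L) flags <- c(flags, FLAG_MONOMORPHIC)

  tab <- probabilityTable(probs, truth)
  po <- concordanceRate(tab)
  pc <- chanceAgreement(tab)
  kap <- iqs(tab)
  flags <- c(flags, attr(kap, "flag"))

  d <- dosageSummaries(probs)
  r2 <- if (sum(keep) >= 2L) squaredCorrelation(d$e, truth) else {
    out <- NA_real_; attr(out, "flag") <- FLAG_DEGENERATE_VARIANCE; out
  }
  flags <- c(flags, attr(r2, "flag"))
  br2 <- if (sum(keep) >= 2L) beagleR2(probs) else NA_real_
  flags <- c(flags, attr(br2, "flag"))
  info <- impute2Info(probs)
  flags <- c(flags, attr(info, "flag"))

  data.frame(
    snp_id = snpId, n_used = sum(keep),
    maf = minorAlleleFrequency(truth),
    concordance = po, chance_agreement = pc,
    iqs = as.numeric(kap), r2 = as.numeric(r2),
    beagle_r2 = as.numeric(br2), impute2_info = as.numeric(info),
    flags = .collapseFlags(flags),
    stringsAsFactors = FALSE)
}
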