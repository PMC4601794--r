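## Minor allele frequency, two-SNP LD r-squared (EM haplotype frequencies on
## unphased genotypes), frequency classes, and 0.01-increment bin summaries.

#' Minor allele frequency from genotyped calls
#'
#' Allele counting on the non-missing calls: \code{p = sum(calls) / (2 n)},
#' returned as \code{min(p, 1 - p)}.
#'
#' @param calls genotype codes in \{0, 1, 2, NA\}.
#' @return MAF in [0, 0.5].
#' @export
minorAlleleFrequency <- function(calls) {
  .assertCalls(calls)
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop("all calls missing")
  p <- sum(calls) / (2 * length(calls))
  min(p, 1 - p)
}

#' Frequency class of a variant
#'
#' Rare: MAF <= 1\%; low frequency: 1\% < MAF <= 5\%; common otherwise.
#' Both boundaries are inclusive on the left class.
#'
#' @param maf minor allele frequency in [0, 0.5] (vectorized).
#' @return Character vector over \code{"RARE"}, \code{"LOW_FREQUENCY"},
#'   \code{"COMMON"}.
#' @export
frequencyClass <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5))
    stop("maf must lie in [0, 0.5]")
  ifelse(maf <= 0.01, "RARE",
         ifelse(maf <= 0.05, "LOW_FREQUENCY", "COMMON"))
}

#' EM haplotype frequencies for two unphased biallelic SNPs
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased genotype
#' pairs.  Every genotype combination except the double heterozygote
#' determines its two haplotypes; the double heterozygote is split between
#' the coupling (AB/ab) and repulsion (Ab/aB) phases in proportion to the
#' current frequency estimates.  Starts at linkage equilibrium and stops when
#' the log-likelihood improves by less than \code{tol} or after
#' \code{maxIter} iterations.
#'
#' @param a,b genotype vectors in \{0, 1, 2, NA\} (coded-allele counts).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @return List: \code{freqs} (named haplotype frequencies \code{ab},
#'   \code{aB}, \code{Ab}, \code{AB}, summing to 1), \code{logLik},
#'   \code{iterations}, \code{converged}, \code{nUsed}.
#' @export
emHaplotypeFrequencies <- function(a, b, tol = 1e-10, maxIter = 1000L) {
  .assertCalls(a, "a"); .assertCalls(b, "b")
  if (length(a) != length(b)) stop("a and b are not aligned")
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2L) stop("fewer than 2 pairwise-complete individuals")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  ## 3 x 3 genotype-pair counts, rows = a in 0:2, cols = b in 0:2
  cnt <- matrix(0, 3L, 3L)
  for (i in 0:2) for (j in 0:2) cnt[i + 1L, j + 1L] <- sum(a == i & b == j)

  pA <- sum(a) / (2 * n)   # freq of coded allele at SNP a
  pB <- sum(b) / (2 * n)
  ## haplotype order: (a-allele, b-allele) in {0,1}^2 -> 00, 01, 10, 11
  h <- c(`00` = (1 - pA) * (1 - pB), `01` = (1 - pA) * pB,
         `10` = pA * (1 - pB), `11` = pA * pB)
  h <- pmax(h, 0); h <- h / sum(h)

  ## per-genotype-pair haplotype-pair composition (phase-known cells).
  ## hapContrib[[i, j]] gives the two haplotype indices contributed by one
  ## individual with genotypes (i-1, j-1); NULL marks the double het.
  hapIndex <- function(x, y) 1L + 2L * x + y   # (a, b) alleles in {0,1}
  contrib <- function(ga, gb) {
    ha <- c(rep(0L, 2 - ga), rep(1L, ga))
    hb <- c(rep(0L, 2 - gb), rep(1L, gb))
    c(hapIndex(ha[1], hb[1]), hapIndex(ha[2], hb[2]))
  }

  logLik <- function(h) {
    ll <- 0
    for (i in 0:2) for (j in 0:2) {
      m <- cnt[i + 1L, j + 1L]
      if (m == 0) next
      if (i == 1L && j == 1L) {
        pr <- 2 * h[1] * h[4] + 2 * h[2] * h[3]
      } else {
        idx <- contrib(i, j)
        pr <- if (idx[1] == idx[2]) h[idx[1]]^2 else 2 * h[idx[1]] * h[idx[2]]
      }
      ll <- ll + m * log(max(pr, .Machine$double.xmin))
    }
    ll
  }

  ll <- logLik(h)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    hapCount <- numeric(4)
    for (i in 0:2) for (j in 0:2) {
      m <- cnt[i + 1L, j + 1L]
      if (m == 0) next
      if (i == 1L && j == 1L) {
        coup <- h[1] * h[4]               # 00/11
        rep_ <- h[2] * h[3]               # 01/10
        tot <- coup + rep_
        w <- if (tot < .Machine$double.xmin) 0.5 else coup / tot
        hapCount[c(1, 4)] <- hapCount[c(1, 4)] + m * w
        hapCount[c(2, 3)] <- hapCount[c(2, 3)] + m * (1 - w)
      } else {
        idx <- contrib(i, j)
        hapCount[idx[1]] <- hapCount[idx[1]] + m
        hapCount[idx[2]] <- hapCount[idx[2]] + m
      }
    }
    h <- hapCount / (2 * n)
    llNew <- logLik(h)
    if (abs(llNew - ll) < tol) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  list(freqs = setNames(h, c("ab", "aB", "Ab", "AB")), logLik = ll,
       iterations = iter, converged = converged, nUsed = n)
}

#' Pairwise LD r-squared between two SNPs
#'
#' Haplotype-based \code{r^2 = D^2 / (pA pa pB pb)} with haplotype
#' frequencies estimated by EM from unphased genotype pairs.  Monomorphic
#' input gives \code{NA}; EM non-convergence returns the best estimate with
#' a \code{converged = FALSE} attribute.
#'
#' @inheritParams emHaplotypeFrequencies
#' @return r-squared in [0, 1], or \code{NA} for monomorphic input.
#' @export
pairwiseR2 <- function(a, b, tol = 1e-10, maxIter = 1000L) {
  keep <- !is.na(a) & !is.na(b)
  aa <- a[keep]; bb <- b[keep]
  if (sum(keep) < 2L) stop("fewer than 2 pairwise-complete individuals")
  if (length(unique(aa)) < 2L || length(unique(bb)) < 2L)
    return(NA_real_)
  em <- emHaplotypeFrequencies(a, b, tol = tol, maxIter = maxIter)
  h <- em$freqs
  pA <- h[["Ab"]] + h[["AB"]]   # coded-allele freq at SNP a
  pB <- h[["aB"]] + h[["AB"]]
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den < DENOM_TOL) return(NA_real_)
  D <- h[["AB"]] - pA * pB
  out <- min(max(D^2 / den, 0), 1)
  if (!em$converged) attr(out, "converged") <- FALSE
  out
}

#' Maximum LD r-squared against a typed panel
#'
#' The largest \code{pairwiseR2} between a target SNP and any typed panel
#' SNP, optionally restricted to a +/- \code{window} bp neighbourhood of
#' \code{targetPos}.  When no panel SNP qualifies (or none gives a defined
#' r-squared) returns \code{NA} with an \code{EMPTY_LD_PANEL} flag
#' attribute.
#'
#' @param target genotype vector of the target SNP.
#' @param panel a \linkS4class{GenotypePanel} of typed SNPs on the same
#'   individuals (same sample order).
#' @param targetPos optional 1-based position of the target (required when
#'   \code{window} is given).
#' @param targetChrom optional chromosome of the target; panel SNPs on other
#'   chromosomes are skipped when given.
#' @param window optional half-width in bp of the LD search window.
#' @return max r-squared in [0, 1], or \code{NA} with flag.
#' @export
maxR2Ld <- function(target, panel, targetPos = NULL, targetChrom = NULL,
                    window = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  if (nSamples(panel) != length(target))
    stop("target and panel are not aligned on individuals")
  idx <- seq_len(nSnps(panel))
  if (!is.null(targetChrom))
    idx <- idx[chromosomes(panel)[idx] == targetChrom]
  if (!is.null(window)) {
    if (is.null(targetPos)) stop("window requires targetPos")
    idx <- idx[abs(positions(panel)[idx] - targetPos) <= window]
  }
  best <- NA_real_
  for (i in idx) {
    r2 <- tryCatch(pairwiseR2(target, genotypeCalls(panel)[i, ]),
                   error = function(e) NA_real_)
    if (!is.na(r2) && (is.na(best) || r2 > best)) best <- as.numeric(r2)
  }
  if (is.na(best)) {
    out <- NA_real_
    attr(out, "flag") <- FLAG_EMPTY_LD_PANEL
    return(out)
  }
  best
}

#' Bin a statistic in 0.01 increments and summarize
#'
#' Bins per-SNP statistic values by MAF or by max LD r-squared in
#' 0.01-increment bins, half-open \code{[lower, lower + 0.01)} with the final
#' bin closed at the axis maximum (0.5 for MAF, 1 for r-squared).  SNPs with
#' an undefined statistic or axis value are excluded.  Empty bins are
#' reported with count 0 and NA mean/sd; singleton bins report sd 0.
#'
#' @param records data.frame of per-SNP records (from \code{\link{assessSnp}}
#'   or the pipeline) carrying the axis column.
#' @param axis \code{"maf"} or \code{"max_r2_ld"}.
#' @param statistic name of the statistic column to summarize.
#' @return data.frame: \code{axis}, \code{bin_lower}, \code{count},
#'   \code{mean}, \code{sd}, one row per bin in axis order.
#' @export
binSummarize <- function(records, axis = c("maf", "max_r2_ld"), statistic) {
  axis <- match.arg(axis)
  if (!axis %in% names(records)) stop("records lack axis column ", axis)
  if (!statistic %in% names(records))
    stop("records lack statistic column ", statistic)
  axisMax <- if (axis == "maf") 0.5 else 1.0
  nBins <- round(axisMax / 0.01)
  v <- records[[axis]]
  s <- records[[statistic]]
  keep <- !is.na(v) & !is.na(s)
  v <- v[keep]; s <- s[keep]
  if (any(v < 0 | v > axisMax + 1e-9))
    stop(axis, " values outside [0, ", axisMax, "]")
  k <- pmin(floor(v * 100 + 1e-9), nBins - 1L)   # final bin closed at top
  out <- data.frame(
    axis = axis,
    bin_lower = (seq_len(nBins) - 1L) / 100,
    count = 0L, mean = NA_real_, sd = NA_real_,
    stringsAsFactors = FALSE)
  if (length(k)) {
    cnt <- tabulate(k + 1L, nbins = nBins)
    out$count <- cnt
    means <- tapply(s, factor(k, levels = 0:(nBins - 1L)), mean)
    sds <- tapply(s, factor(k, levels = 0:(nBins - 1L)), sd)
    out$mean <- as.numeric(means)
    out$sd <- as.numeric(sds)
    out$sd[out$count == 1L] <- 0        # singleton bins: no dispersion
  }
  out
}
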