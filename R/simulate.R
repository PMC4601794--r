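## Synthetic-data generator: Hardy-Weinberg truth genotypes across a MAF
## spectrum, imputed probability vectors of controllable fidelity (including
## a chance-level and a major-homozygote imputer), and typed proxy SNPs with
## controllable LD to each target.  All randomness flows from the config
## seed; the global RNG state is never touched.

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' i.i.d. genotype draws with class probabilities ((1-q)^2, 2q(1-q), q^2)
#' at coded-allele frequency q = \code{maf}.
#'
#' @param maf coded (minor) allele frequency in (0, 0.5].
#' @param n number of individuals.
#' @param seed integer RNG seed.
#' @return Integer vector of calls in \{0, 1, 2\}.
#' @export
simulateTruthGenotypes <- function(maf, n, seed) {
  if (is.na(maf) || maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (n < 1L) stop("n must be >= 1")
  withr::with_seed(as.integer(seed), .rHweGenotypes(maf, n))
}

.rHweGenotypes <- function(maf, n) {
  ## two independent allele draws per individual
  rbinom(n, 2L, maf)
}

.rDirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  s <- rowSums(x)
  zero <- s <= 0
  if (any(zero)) {           # all-zero gamma draws at tiny alpha
    x[zero, ] <- rep(alpha / sum(alpha), each = sum(zero))
    s[zero] <- rowSums(x[zero, , drop = FALSE])
  }
  x / s
}

#' Simulate imputed genotype probabilities for one SNP
#'
#' Generates one probability row per individual according to the configured
#' imputer: \code{BLEND} mixes a point mass on the true genotype (weight
#' \code{fidelity}) with a Dirichlet draw centred on the Hardy-Weinberg
#' genotype frequencies at the SNP's MAF (sharpness \code{concentration});
#' \code{CHANCE} is the fidelity-0 case, independent of truth;
#' \code{MAJOR_HOMOZYGOTE} puts probability 1 on AA for everyone, the
#' chance-level caller that still attains high concordance at rare
#' variants.
#'
#' @param truth integer truth calls in \{0, 1, 2\}.
#' @param maf the SNP's allele frequency (centres the chance component).
#' @param config a \linkS4class{SimulationConfig} (its \code{seed} seeds
#'   the draw unless \code{seed} is given).
#' @param seed optional seed override.
#' @return N x 3 row-stochastic probability matrix.
#' @export
simulateImputedProbabilities <- function(truth, maf, config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  .assertCalls(truth, "truth")
  if (anyNA(truth)) stop("simulated truth must be complete")
  n <- length(truth)
  seed <- as.integer(seed %||% config@seed)
  if (config@imputerMode == "MAJOR_HOMOZYGOTE")
    return(cbind(rep(1, n), 0, 0))
  lambda <- if (config@imputerMode == "CHANCE") 0 else config@fidelity
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  withr::with_seed(seed, {
    chance <- .rDirichlet(n, config@concentration * hwe)
    point <- matrix(0, n, 3L)
    point[cbind(seq_len(n), truth + 1L)] <- 1
    lambda * point + (1 - lambda) * chance
  })
}

#' Simulate a typed proxy SNP in LD with a target
#'
#' Copies the target's genotypes and flips each of the 2n allele copies to
#' the alternate allele independently with probability \code{epsilon}:
#' \code{epsilon = 0} gives a perfect tag SNP (r-squared 1), 0.5 destroys
#' all LD.
#'
#' @param truth integer target calls in \{0, 1, 2\}.
#' @param epsilon per-allele flip rate in [0, 0.5].
#' @param seed integer RNG seed.
#' @return Integer vector of proxy calls.
#' @export
simulateLinkedTypedSnp <- function(truth, epsilon, seed) {
  .assertCalls(truth, "truth")
  if (anyNA(truth)) stop("simulated truth must be complete")
  if (epsilon < 0 || epsilon > 0.5) stop("epsilon must lie in [0, 0.5]")
  n <- length(truth)
  withr::with_seed(as.integer(seed), {
    ## decompose each genotype into two allele copies, flip independently
    a1 <- as.integer(truth >= 1L)          # one haplotype carries B if >= 1
    a2 <- as.integer(truth == 2L)
    ## heterozygotes: one copy of each allele; assignment to a1/a2 immaterial
    f1 <- rbinom(n, 1L, epsilon)
    f2 <- rbinom(n, 1L, epsilon)
    as.integer(abs(a1 - f1) + abs(a2 - f2))
  })
}

#' Simulate a full masking-experiment dataset
#'
#' Draws \code{nSnps} target SNPs with MAFs from the configured spectrum
#' (log-uniform over \code{mafRange} unless explicit \code{mafs} are given),
#' HWE truth genotypes, imputed probabilities under the configured imputer,
#' and one typed proxy SNP per target at the configured LD flip rate.
#' Targets sit at 1 kb spacing on chromosome "1" starting at 1,000,000 with
#' each proxy 500 bp downstream.  Deterministic under \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return List: \code{truth} (\linkS4class{GenotypePanel} of targets),
#'   \code{imputed} (\linkS4class{ImputedPanel}), \code{typed}
#'   (\linkS4class{GenotypePanel} of proxies), \code{mafs} (the drawn
#'   spectrum).
#' @export
simulateComparisonDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  m <- config@nSnps
  n <- config@nIndividuals
  withr::with_seed(config@seed, {
    mafs <- if (length(config@mafs)) {
      if (length(config@mafs) != m)
        stop("explicit mafs must have length nSnps")
      config@mafs
    } else {
      exp(runif(m, log(config@mafRange[1]), log(config@mafRange[2])))
    }
    calls <- matrix(0L, m, n)
    probs <- vector("list", m)
    proxy <- matrix(0L, m, n)
    for (i in seq_len(m)) {
      calls[i, ] <- .rHweGenotypes(mafs[i], n)
      snpSeed <- sample.int(.Machine$integer.max, 1L)
      probs[[i]] <- simulateImputedProbabilities(calls[i, ], mafs[i], config,
                                                 seed = snpSeed)
      proxy[i, ] <- simulateLinkedTypedSnp(calls[i, ], config@ldFlipRate,
                                           seed = sample.int(
                                             .Machine$integer.max, 1L))
    }
  })
  sampleIds <- sprintf("S%04d", seq_len(n))
  pos <- 1000000L + 1000L * seq_len(m)
  ids <- sprintf("snp%05d", seq_len(m))
  truth <- GenotypePanel(chrom = rep("1", m), pos = pos, snpId = ids,
                         ref = rep("A", m), alt = rep("G", m),
                         calls = calls, sampleIds = sampleIds)
  typed <- GenotypePanel(chrom = rep("1", m), pos = pos + 500L,
                         snpId = sprintf("tag%05d", seq_len(m)),
                         ref = rep("C", m), alt = rep("T", m),
                         calls = proxy, sampleIds = sampleIds)
  imputed <- ImputedPanel(chrom = rep("1", m), pos = pos, snpId = ids,
                          alleleA = rep("A", m), alleleB = rep("G", m),
                          probs = probs, sampleIds = sampleIds,
                          dialect = "SIMULATED")
  list(truth = truth, imputed = imputed, typed = typed, mafs = mafs)
}
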