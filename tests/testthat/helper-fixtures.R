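# Shared fixture builders: everything is generated in code, seeded locally.

# random row-stochastic N x 3 probability matrix
randomProbMatrix <- function(n, sharp = 1) {
  x <- matrix(rgamma(3 * n, shape = sharp), ncol = 3)
  x / rowSums(x)
}

# degenerate probability matrix putting mass 1 on each truth call
degenerateProbs <- function(truth) {
  p <- matrix(0, length(truth), 3)
  p[cbind(seq_along(truth), truth + 1L)] <- 1
  p
}

# random truth calls covering all classes where possible
randomTruth <- function(n, pMissing = 0) {
  calls <- sample(0:2, n, replace = TRUE)
  if (pMissing > 0)
    calls[runif(n) < pMissing] <- NA_integer_
  calls
}

# small truth panel with explicit coordinates
makePanel <- function(callsMatrix, chrom = "1",
                      pos = seq_len(nrow(callsMatrix)) * 100L,
                      ref = "A", alt = "G") {
  m <- nrow(callsMatrix)
  GenotypePanel(chrom = rep(chrom, m), pos = pos,
                snpId = sprintf("s%03d", seq_len(m)),
                ref = rep(ref, m), alt = rep(alt, m),
                calls = callsMatrix,
                sampleIds = sprintf("I%03d", seq_len(ncol(callsMatrix))))
}

# brute-force contingency table by explicit double loop (independent oracle)
bruteForceTable <- function(probs, truth) {
  cells <- matrix(0, 3, 3)
  for (n in seq_along(truth)) {
    if (is.na(truth[n])) next
    for (i in 1:3) {
      cells[i, truth[n] + 1] <- cells[i, truth[n] + 1] + probs[n, i]
    }
  }
  cells
}

# genotypes from explicit haplotype pairs (phase known by construction)
genotypesFromHaplotypes <- function(hapCounts) {
  # hapCounts: named counts of ordered haplotype pairs, names like "00|11"
  a <- integer(0); b <- integer(0)
  for (nm in names(hapCounts)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    h1 <- as.integer(strsplit(pair[1], "")[[1]])
    h2 <- as.integer(strsplit(pair[2], "")[[1]])
    k <- hapCounts[[nm]]
    a <- c(a, rep(h1[1] + h2[1], k))
    b <- c(b, rep(h1[2] + h2[2], k))
  }
  list(a = a, b = b)
}

# closed-form r2 from a haplotype frequency table
r2FromHaplotypeFreqs <- function(f) {
  # f named: ab, aB, Ab, AB
  pA <- f[["Ab"]] + f[["AB"]]
  pB <- f[["aB"]] + f[["AB"]]
  D <- f[["AB"]] - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
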