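test_that("minor allele frequency counts alleles over non-missing calls", {
  expect_equal(minorAlleleFrequency(c(rep(0, 99), 1)), 1 / 200)
  expect_equal(minorAlleleFrequency(c(rep(0, 25), rep(1, 50), rep(2, 25))),
               0.5)
  # folded to the minor side
  expect_equal(minorAlleleFrequency(c(rep(2, 9), 1)), 1 / 20)

  # missing entries drop out of the denominator (manual tally oracle)
  calls <- c(0, 1, 2, NA, 1, NA, 0)
  expect_equal(minorAlleleFrequency(calls), sum(calls, na.rm = TRUE) / (2 * 5))

  expect_error(minorAlleleFrequency(c(NA_integer_, NA_integer_)), "missing")
})

test_that("frequency classes use inclusive boundaries at 1% and 5%", {
  expect_equal(frequencyClass(0.01), "RARE")
  expect_equal(frequencyClass(0.0100001), "LOW_FREQUENCY")
  expect_equal(frequencyClass(0.05), "LOW_FREQUENCY")
  expect_equal(frequencyClass(0.2), "COMMON")
  expect_equal(frequencyClass(c(0, 0.5)), c("RARE", "COMMON"))
  expect_error(frequencyClass(0.6), "0.5")
})

test_that("EM haplotype frequencies are proper and recover known phase", {
  # configuration free of double heterozygotes: phase is determined, so the
  # EM answer must match the closed-form haplotype-count estimate
  hapCounts <- c("00|00" = 20, "11|11" = 10, "00|01" = 15, "01|01" = 5,
                 "10|10" = 8, "01|11" = 6, "00|10" = 7)
  g <- genotypesFromHaplotypes(hapCounts)
  expect_false(any(g$a == 1 & g$b == 1))   # no double heterozygotes
  em <- emHaplotypeFrequencies(g$a, g$b)
  expect_true(em$converged)
  expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
  expect_true(all(em$freqs >= 0))
  # direct haplotype tally from the known phase
  tally <- c("00" = 0, "01" = 0, "10" = 0, "11" = 0)
  for (nm in names(hapCounts)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    tally[pair[1]] <- tally[pair[1]] + hapCounts[[nm]]
    tally[pair[2]] <- tally[pair[2]] + hapCounts[[nm]]
  }
  expected <- setNames(as.numeric(tally / sum(tally)),
                       c("ab", "aB", "Ab", "AB"))
  expect_equal(em$freqs, expected, tolerance = 1e-6)
  expect_equal(as.numeric(pairwiseR2(g$a, g$b)),
               r2FromHaplotypeFreqs(expected), tolerance = 1e-6)
})

test_that("pairwise r2 behaves as an LD measure", {
  set.seed(21)
  a <- simulateTruthGenotypes(0.3, 400, 211)
  expect_equal(as.numeric(pairwiseR2(a, a)), 1, tolerance = 1e-9)

  # independence: two unlinked SNPs at n = 10,000 give r2 below 0.01
  x <- simulateTruthGenotypes(0.3, 10000, 212)
  y <- simulateTruthGenotypes(0.2, 10000, 213)
  expect_lt(as.numeric(pairwiseR2(x, y)), 0.01)

  # symmetry and allele-relabelling invariance
  b <- simulateLinkedTypedSnp(a, 0.1, 214)
  r <- as.numeric(pairwiseR2(a, b))
  expect_equal(r, as.numeric(pairwiseR2(b, a)), tolerance = 1e-10)
  expect_equal(r, as.numeric(pairwiseR2(2L - a, b)), tolerance = 1e-10)
  expect_equal(r, as.numeric(pairwiseR2(a, 2L - b)), tolerance = 1e-10)

  # monomorphic input is undefined
  expect_true(is.na(pairwiseR2(rep(1L, 10), randomTruth(10))))
})

test_that("max r2 against a typed panel is the exhaustive maximum", {
  set.seed(22)
  target <- simulateTruthGenotypes(0.25, 200, 221)

  # perfect proxy present
  panel <- makePanel(rbind(simulateLinkedTypedSnp(target, 0.2, 222), target))
  expect_equal(as.numeric(maxR2Ld(target, panel)), 1, tolerance = 1e-9)

  # empty panel: flagged undefined
  empty <- subsetSnps(panel, integer(0))
  out <- maxR2Ld(target, empty)
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "EMPTY_LD_PANEL")

  # exhaustive max over 20 random panel SNPs
  calls <- t(vapply(1:20, function(i)
    simulateLinkedTypedSnp(target, runif(1, 0, 0.5), 2200 + i),
    integer(200)))
  panel20 <- makePanel(calls)
  each <- vapply(1:20, function(i)
    as.numeric(pairwiseR2(target, calls[i, ])), 0)
  expect_equal(as.numeric(maxR2Ld(target, panel20)), max(each, na.rm = TRUE),
               tolerance = 1e-12)

  # window restriction drops distant partners
  near <- maxR2Ld(target, panel20, targetPos = 150L, targetChrom = "1",
                  window = 300L)
  eachNear <- each[abs(seq_len(20) * 100L - 150L) <= 300L]
  expect_equal(as.numeric(near), max(eachNear, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("expected proxy LD decreases with the flip rate", {
  set.seed(23)
  eps <- c(0, 0.05, 0.1, 0.2)
  meanR2 <- vapply(eps, function(e) {
    mean(vapply(1:100, function(r) {
      a <- simulateTruthGenotypes(0.3, 300, 23000 + r)
      b <- simulateLinkedTypedSnp(a, e, 24000 + r)
      out <- pairwiseR2(a, b)
      if (is.na(out)) 0 else as.numeric(out)
    }, 0))
  }, 0)
  expect_true(all(diff(meanR2) < 0))
  expect_equal(meanR2[1], 1, tolerance = 1e-9)
  # epsilon = 0.5 destroys LD entirely at large n
  a <- simulateTruthGenotypes(0.3, 10000, 235)
  b <- simulateLinkedTypedSnp(a, 0.5, 236)
  expect_lt(as.numeric(pairwiseR2(a, b)), 0.01)
})

test_that("bin summaries follow the half-open 0.01 convention", {
  rec <- data.frame(
    maf = c(0.015, 0.015, 0.015, 0.5, 0.049999, 0.02),
    max_r2_ld = c(0.2, 0.2, 0.2, 1.0, 0.35, NA),
    iqs = c(0.5, 0.5, 0.5, 0.9, 0.7, 0.3))

  b <- binSummarize(rec, axis = "maf", statistic = "iqs")
  expect_equal(nrow(b), 50)
  # identical values in one bin: sd 0
  expect_equal(b$count[b$bin_lower == 0.01], 3L)
  expect_equal(b$sd[b$bin_lower == 0.01], 0)
  expect_equal(b$mean[b$bin_lower == 0.01], 0.5)
  # final bin closed at the top of the MAF axis
  expect_equal(b$count[b$bin_lower == 0.49], 1L)
  # value just below a boundary stays in the lower bin
  expect_equal(b$count[b$bin_lower == 0.04], 1L)
  # singleton bins report sd 0, empty bins NA
  expect_equal(b$sd[b$bin_lower == 0.49], 0)
  expect_true(is.na(b$mean[b$bin_lower == 0.3]))
  expect_equal(b$count[b$bin_lower == 0.3], 0L)

  # r2 axis: undefined axis values excluded; final bin closed at 1
  b2 <- binSummarize(rec, axis = "max_r2_ld", statistic = "iqs")
  expect_equal(nrow(b2), 100)
  expect_equal(sum(b2$count), sum(!is.na(rec$max_r2_ld)))
  expect_equal(b2$count[b2$bin_lower == 0.99], 1L)

  # random records match an independent group-by computation
  set.seed(24)
  rr <- data.frame(maf = runif(300, 0, 0.5), iqs = runif(300, -0.2, 1),
                   max_r2_ld = runif(300))
  b3 <- binSummarize(rr, axis = "maf", statistic = "iqs")
  grp <- split(rr$iqs, floor(pmin(rr$maf, 0.4999999) * 100 + 1e-9))
  for (k in names(grp)) {
    i <- as.integer(k) + 1L
    expect_equal(b3$count[i], length(grp[[k]]))
    expect_equal(b3$mean[i], mean(grp[[k]]), tolerance = 1e-12)
    if (length(grp[[k]]) > 1)
      expect_equal(b3$sd[i], sd(grp[[k]]), tolerance = 1e-12)
  }
  expect_equal(sum(b3$count), 300L)
})
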