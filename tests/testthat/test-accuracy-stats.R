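test_that("probability table places mass by truth class and conserves it", {
  # identity case: degenerate probabilities on the truth
  tab <- probabilityTable(rbind(c(1, 0, 0), c(0, 1, 0)), c(0, 1))
  expect_equal(diag(tab@cells), c(1, 1, 0))
  expect_equal(sum(tab@cells) - sum(diag(tab@cells)), 0)
  expect_equal(tab@nUsed, 2L)

  # a single individual's row lands entirely in its actual-class column
  tab1 <- probabilityTable(rbind(c(0.2, 0.5, 0.3)), 0)
  expect_equal(tab1@cells[, 1], c(0.2, 0.5, 0.3))
  expect_equal(tab1@cells[, 2:3], matrix(0, 3, 2))

  # random matrices match an independent double-loop accumulation,
  # with missing truth excluded and mass conserved
  set.seed(11)
  for (rep in 1:5) {
    probs <- randomProbMatrix(50)
    truth <- randomTruth(50, pMissing = 0.1)
    tab <- probabilityTable(probs, truth)
    expect_equal(tab@cells, bruteForceTable(probs, truth), tolerance = 1e-12)
    expect_equal(sum(tab@cells), sum(!is.na(truth)), tolerance = 1e-6)
    expect_equal(tab@classCounts,
                 tabulate(truth[!is.na(truth)] + 1L, 3L))
  }

  expect_error(probabilityTable(randomProbMatrix(3), c(0, 1)), "aligned")
  expect_error(probabilityTable(randomProbMatrix(2),
                                c(NA_integer_, NA_integer_)),
               "non-missing")
})

test_that("concordance and chance agreement follow the table margins", {
  # all mass on the diagonal of a polymorphic truth
  truth <- c(rep(0, 6), rep(1, 3), 2)
  tab <- probabilityTable(degenerateProbs(truth), truth)
  expect_equal(concordanceRate(tab), 1)

  # 99 AA + 1 AB truth, imputer always says AA with probability 1
  truth <- c(rep(0, 99), 1)
  alwaysAA <- matrix(rep(c(1, 0, 0), 100), ncol = 3, byrow = TRUE)
  tab <- probabilityTable(alwaysAA, truth)
  expect_equal(concordanceRate(tab), 0.99)
  expect_equal(chanceAgreement(tab), 99 * 100 / 100^2)

  # single-class saturation
  tabAA <- probabilityTable(matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE),
                            rep(0, 5))
  expect_equal(chanceAgreement(tabAA), 1)

  # random tables match direct margin arithmetic
  set.seed(12)
  for (rep in 1:5) {
    probs <- randomProbMatrix(40)
    truth <- randomTruth(40)
    tab <- probabilityTable(probs, truth)
    n <- tab@nUsed
    expect_equal(concordanceRate(tab), sum(diag(tab@cells)) / n,
                 tolerance = 1e-12)
    expect_equal(chanceAgreement(tab),
                 sum(colSums(tab@cells) * rowSums(tab@cells)) / n^2,
                 tolerance = 1e-12)
  }
})

test_that("IQS is the chance-corrected agreement with its boundary cases", {
  # perfect polymorphic match scores exactly 1
  truth <- c(rep(0, 6), rep(1, 3), 2)
  expect_equal(iqs(probabilityTable(degenerateProbs(truth), truth)), 1)

  # always-AA on nearly monomorphic truth: agreement equals chance
  truth <- c(rep(0, 99), 1)
  alwaysAA <- matrix(rep(c(1, 0, 0), 100), ncol = 3, byrow = TRUE)
  expect_equal(as.numeric(iqs(probabilityTable(alwaysAA, truth))), 0)

  # full class swap on a balanced SNP: maximal disagreement
  truth <- c(rep(0, 50), rep(2, 50))
  swapped <- degenerateProbs(ifelse(truth == 0, 2, 0))
  expect_equal(as.numeric(iqs(probabilityTable(swapped, truth))), -1)

  # monomorphic truth: chance agreement is 1, score undefined
  mono <- iqs(probabilityTable(degenerateProbs(rep(0, 10)), rep(0, 10)))
  expect_true(is.na(mono))
  expect_equal(attr(mono, "flag"), "MONOMORPHIC")
})

test_that("IQS equals an independent evaluation and never beats concordance", {
  set.seed(13)
  violations <- 0L
  for (rep in 1:2000) {
    probs <- randomProbMatrix(sample(5:30, 1), sharp = runif(1, 0.2, 3))
    truth <- randomTruth(nrow(probs))
    tab <- probabilityTable(probs, truth)
    po <- concordanceRate(tab)
    pc <- chanceAgreement(tab)
    kap <- iqs(tab)
    if (is.na(kap)) next
    # separate code path for the kappa form
    expect_equal(as.numeric(kap), (po - pc) / (1 - pc), tolerance = 1e-12)
    if (as.numeric(kap) > po + 1e-12) violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("dosage summaries implement the stated arithmetic and tie rule", {
  d <- dosageSummaries(rbind(c(0, 0, 1)))
  expect_equal(d$e, 2); expect_equal(d$f, 4); expect_equal(d$z, 2L)

  d <- dosageSummaries(rbind(c(0.2, 0.5, 0.3)))
  expect_equal(d$e, 1.1)
  expect_equal(d$f, 0.5 + 4 * 0.3)
  expect_equal(d$z, 1L)

  # exact tie: lowest genotype index among the maxima wins
  d <- dosageSummaries(rbind(rep(1, 3) / 3))
  expect_equal(d$e, 1)
  expect_equal(d$f, 5 / 3)
  expect_equal(d$z, 0L)
  d2 <- dosageSummaries(rbind(c(0.2, 0.4, 0.4)))
  expect_equal(d2$z, 1L)

  # pure function: Jensen bound and theta from mean dosage, reproducibly
  set.seed(14)
  p <- randomProbMatrix(100)
  d <- dosageSummaries(p)
  expect_true(all(d$f - d$e^2 >= -1e-12))
  expect_equal(d$thetaHat, mean(d$e) / 2)
  expect_identical(d, dosageSummaries(p))
})

test_that("squared correlation matches Pearson and flags degeneracy", {
  truth <- c(0, 1, 2, 1, 0, 2, 1)
  expect_equal(squaredCorrelation(truth, truth), 1)
  expect_equal(squaredCorrelation(2 - truth, truth), 1)

  const <- squaredCorrelation(rep(1.3, 7), truth)
  expect_true(is.na(const))
  expect_equal(attr(const, "flag"), "DEGENERATE_VARIANCE")

  expect_error(squaredCorrelation(c(1, NA), c(NA, 1)), "fewer than 2")

  set.seed(15)
  for (rep in 1:20) {
    x <- runif(30, 0, 2)
    y <- randomTruth(30, pMissing = 0.1)
    expect_equal(as.numeric(squaredCorrelation(x, y)),
                 cor(x, y, use = "pairwise.complete.obs")^2,
                 tolerance = 1e-10)
    cc <- correlationComponents(x, y)
    expect_gte(cc$SSxx, 0); expect_gte(cc$SSyy, 0)
    expect_gte(cc$SSE, -1e-10)
    expect_lte(cc$SSE, cc$SSyy + 1e-10)
  }
})

test_that("allelic R2 follows the variance-form evaluation", {
  # degenerate certainty with more than one class: exactly 1
  truth <- c(0, 0, 1, 2, 1)
  expect_equal(beagleR2(degenerateProbs(truth)), 1)

  # constant best guess: undefined
  same <- matrix(rep(c(0.1, 0.7, 0.2), 10), ncol = 3, byrow = TRUE)
  out <- beagleR2(same)
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "DEGENERATE_VARIANCE")

  expect_error(beagleR2(rbind(c(1, 0, 0))), "at least 2")

  # random matrices match a term-by-term oracle with sum(z^2) in the
  # z-variance term
  set.seed(16)
  for (rep in 1:20) {
    p <- randomProbMatrix(25)
    e <- p[, 2] + 2 * p[, 3]
    f <- p[, 2] + 4 * p[, 3]
    z <- apply(p, 1, which.max) - 1
    n <- nrow(p)
    num <- (sum(z * e) - sum(z) * sum(e) / n)^2
    den <- (sum(f) - sum(e)^2 / n) * (sum(z^2) - sum(z)^2 / n)
    if (den < 1e-12) next
    expect_equal(as.numeric(beagleR2(p)), min(max(num / den, 0), 1),
                 tolerance = 1e-10)
  }
})

test_that("INFO measures dosage certainty against binomial variance", {
  truth <- c(0, 1, 2, 1)
  expect_equal(impute2Info(degenerateProbs(truth)), 1)

  # uniform rows: theta = 1/2, mean dosage variance 2/3
  unif <- matrix(rep(1 / 3, 30), ncol = 3)
  expect_equal(impute2Info(unif), 1 - (2 / 3) / 0.5, tolerance = 1e-12)

  # boundary allele frequency: undefined
  aa <- matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE)
  out <- impute2Info(aa)
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "THETA_BOUNDARY")

  # term-by-term oracle on random input
  set.seed(17)
  for (rep in 1:20) {
    p <- randomProbMatrix(25)
    e <- p[, 2] + 2 * p[, 3]
    f <- p[, 2] + 4 * p[, 3]
    th <- mean(e) / 2
    expect_equal(impute2Info(p),
                 1 - sum(f - e^2) / (2 * nrow(p) * th * (1 - th)),
                 tolerance = 1e-10)
  }
})

test_that("row normalization repairs rounded rows and rejects bad ones", {
  p <- rbind(c(0.33, 0.33, 0.33))       # sums to 0.99 < tolerance 1e-4 away?
  expect_error(probabilityTable(p, 0), "row sum")
  pOk <- rbind(c(0.33335, 0.33335, 0.3333))
  tab <- probabilityTable(pOk, 0)
  expect_equal(sum(tab@cells), 1, tolerance = 1e-12)
})

test_that("assessSnp aggregates the standalone statistics faithfully", {
  # perfect polymorphic imputation: all five statistics are 1
  truth <- c(rep(0, 5), rep(1, 3), rep(2, 2))
  rec <- assessSnp(degenerateProbs(truth), truth)
  expect_equal(rec$concordance, 1)
  expect_equal(rec$iqs, 1)
  expect_equal(rec$r2, 1)
  expect_equal(rec$beagle_r2, 1)
  expect_equal(rec$impute2_info, 1)
  expect_equal(rec$flags, "")

  # monomorphic truth: flagged, chance-corrected score undefined
  mono <- assessSnp(degenerateProbs(rep(0, 8)), rep(0, 8))
  expect_true(grepl("MONOMORPHIC", mono$flags))
  expect_true(is.na(mono$iqs))

  # componentwise equality with the standalone operations on random input
  set.seed(18)
  for (rep in 1:10) {
    probs <- randomProbMatrix(40)
    truth <- randomTruth(40, pMissing = 0.1)
    if (sum(!is.na(truth)) < 3) next
    rec <- assessSnp(probs, truth)
    keep <- !is.na(truth)
    tab <- probabilityTable(probs[keep, ], truth[keep])
    expect_equal(rec$concordance, concordanceRate(tab))
    expect_equal(rec$chance_agreement, chanceAgreement(tab))
    expect_equal(rec$iqs, as.numeric(iqs(tab)))
    d <- dosageSummaries(probs[keep, ])
    expect_equal(rec$r2,
                 as.numeric(squaredCorrelation(d$e, truth[keep])))
    expect_equal(rec$beagle_r2, as.numeric(beagleR2(probs[keep, ])))
    expect_equal(rec$impute2_info, as.numeric(impute2Info(probs[keep, ])))
    expect_equal(rec$n_used, sum(keep))
    if (!is.na(rec$iqs)) expect_lte(rec$iqs, rec$concordance + 1e-12)
  }
})
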