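#' Panel of true genotype calls
#'
#' An S4 container for biallelic SNP genotype calls on a set of individuals:
#' one row per SNP (ordered by chromosome then 1-based position, unique
#' positions), one column per sample.  Calls count copies of the coded (ALT/B)
#' allele: 0 = AA, 1 = AB, 2 = BB, \code{NA} = missing.  This is the "truth"
#' side of every accuracy comparison, and also the representation of a typed
#' SNP panel used for LD annotation.
#'
#' @slot chrom character, chromosome per SNP.
#' @slot pos integer, 1-based base-pair position per SNP.
#' @slot snpId character, SNP identifiers.
#' @slot ref,alt character, reference (A) and coded/alternate (B) alleles.
#' @slot calls integer matrix, SNPs x samples, values in \{0, 1, 2, NA\}.
#' @slot sampleIds character, unique sample identifiers (column order).
#'
#' @export
setClass("GenotypePanel",
  representation(
    chrom = "character",
    pos = "integer",
    snpId = "character",
    ref = "character",
    alt = "character",
    calls = "matrix",
    sampleIds = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  m <- length(object@snpId)
  msgs <- character()
  if (length(object@chrom) != m || length(object@pos) != m ||
      length(object@ref) != m || length(object@alt) != m)
    msgs <- c(msgs, "per-SNP slots must have equal length")
  if (nrow(object@calls) != m)
    msgs <- c(msgs, "calls must have one row per SNP")
  if (ncol(object@calls) != length(object@sampleIds))
    msgs <- c(msgs, "calls must have one column per sample")
  if (anyDuplicated(object@sampleIds))
    msgs <- c(msgs, "sampleIds must be unique")
  if (m > 0) {
    if (any(object@pos <= 0L)) msgs <- c(msgs, "positions must be positive")
    if (anyDuplicated(paste(object@chrom, object@pos)))
      msgs <- c(msgs, "duplicate (chrom, pos) sites")
    o <- order(object@chrom, object@pos)
    if (!identical(o, seq_len(m)))
      msgs <- c(msgs, "SNPs must be ordered by (chrom, pos)")
    v <- object@calls
    if (!all(is.na(v) | v == 0L | v == 1L | v == 2L))
      msgs <- c(msgs, "calls must be in {0, 1, 2, NA}")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' Rows are sorted by (chromosome, position); \code{calls} may be integer or
#' numeric and is stored as an integer matrix.
#'
#' @param chrom,pos,snpId,ref,alt per-SNP metadata vectors.
#' @param calls SNPs x samples matrix of genotype codes in \{0, 1, 2, NA\}.
#' @param sampleIds sample identifiers (defaults to column names or S1..SN).
#' @return A \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(chrom, pos, snpId, ref, alt, calls,
                          sampleIds = NULL) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(snpId))
  if (is.null(sampleIds))
    sampleIds <- colnames(calls) %||% sprintf("S%03d", seq_len(ncol(calls)))
  mode(calls) <- "integer"
  dimnames(calls) <- NULL
  o <- order(chrom, pos)
  new("GenotypePanel",
      chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
      snpId = as.character(snpId)[o], ref = as.character(ref)[o],
      alt = as.character(alt)[o],
      calls = calls[o, , drop = FALSE],
      sampleIds = as.character(sampleIds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Panel of imputed genotype probabilities
#'
#' Per-SNP N x 3 posterior genotype probability matrices (columns AA, AB, BB
#' in the coded-allele orientation given by \code{alleleA}/\code{alleleB}),
#' plus the accuracy score the imputation program itself reported for each
#' SNP, when one was parsed (\code{NA} otherwise).
#'
#' @slot chrom,pos,snpId,alleleA,alleleB per-SNP metadata.
#' @slot probs list of N x 3 row-stochastic matrices, one per SNP.
#' @slot sampleIds character, shared sample ordering of all matrices.
#' @slot dialect one of \code{"VCF_GP"}, \code{"IMPUTE2_GEN"},
#'   \code{"BEAGLE_GPROBS"}, \code{"SIMULATED"}.
#' @slot programScores numeric per-SNP externally reported score.
#'
#' @export
setClass("ImputedPanel",
  representation(
    chrom = "character",
    pos = "integer",
    snpId = "character",
    alleleA = "character",
    alleleB = "character",
    probs = "list",
    sampleIds = "character",
    dialect = "character",
    programScores = "numeric"
  )
)

setValidity("ImputedPanel", function(object) {
  m <- length(object@snpId)
  msgs <- character()
  if (length(object@probs) != m || length(object@chrom) != m ||
      length(object@pos) != m || length(object@alleleA) != m ||
      length(object@alleleB) != m || length(object@programScores) != m)
    msgs <- c(msgs, "per-SNP slots must have equal length")
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds))
    msgs <- c(msgs, "sampleIds must be unique")
  bad <- vapply(object@probs, function(p) {
    !is.matrix(p) || nrow(p) != n || ncol(p) != 3L ||
      anyNA(p) || any(p < 0) || any(p > 1) ||
      any(abs(rowSums(p) - 1) > ROW_SUM_TOL)
  }, logical(1))
  if (any(bad))
    msgs <- c(msgs, "every probs entry must be an N x 3 row-stochastic matrix")
  if (length(object@dialect) != 1L)
    msgs <- c(msgs, "dialect must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImputedPanel
#'
#' @param chrom,pos,snpId,alleleA,alleleB per-SNP metadata vectors.
#' @param probs list of N x 3 probability matrices (rows renormalized under
#'   the row-sum tolerance).
#' @param sampleIds sample identifiers in matrix row order.
#' @param dialect source dialect label.
#' @param programScores optional per-SNP program-reported score.
#' @return An \linkS4class{ImputedPanel}.
#' @export
ImputedPanel <- function(chrom, pos, snpId, alleleA, alleleB, probs,
                         sampleIds, dialect = "SIMULATED",
                         programScores = NULL) {
  probs <- lapply(probs, normalizeProbRows)
  if (is.null(programScores)) programScores <- rep(NA_real_, length(snpId))
  new("ImputedPanel",
      chrom = as.character(chrom), pos = as.integer(pos),
      snpId = as.character(snpId),
      alleleA = as.character(alleleA), alleleB = as.character(alleleB),
      probs = probs, sampleIds = as.character(sampleIds),
      dialect = dialect, programScores = as.numeric(programScores))
}

#' Imputed-versus-actual probability contingency table
#'
#' The 3 x 3 table whose cell (i, j) is the total imputed probability mass of
#' class i summed over individuals whose actual genotype class is j.  Column
#' totals are therefore the actual genotype class counts, and the grand total
#' is the number of individuals with non-missing truth.  Concordance rate,
#' chance agreement and the Imputation Quality Score are all functions of
#' this table.
#'
#' @slot cells 3 x 3 numeric matrix (rows = imputed class, cols = actual).
#' @slot classCounts integer, actual class counts (N1, N2, N3).
#' @slot nUsed integer, number of non-missing individuals.
#'
#' @export
setClass("ProbabilityTable",
  representation(cells = "matrix", classCounts = "integer", nUsed = "integer"))

setValidity("ProbabilityTable", function(object) {
  msgs <- character()
  if (!identical(dim(object@cells), c(3L, 3L)))
    msgs <- c(msgs, "cells must be 3 x 3")
  if (any(object@cells < -1e-9)) msgs <- c(msgs, "cells must be non-negative")
  if (length(object@classCounts) != 3L)
    msgs <- c(msgs, "classCounts must have length 3")
  if (sum(object@classCounts) != object@nUsed)
    msgs <- c(msgs, "classCounts must sum to nUsed")
  if (object@nUsed > 0 &&
      abs(sum(object@cells) - object@nUsed) > 1e-6 * max(1, object@nUsed))
    msgs <- c(msgs, "probability mass must equal the number of individuals")
  if (any(abs(colSums(object@cells) - object@classCounts) >
          1e-6 * max(1, object@nUsed)))
    msgs <- c(msgs, "column totals must equal the actual class counts")
  if (length(msgs)) msgs else TRUE
})

#' Result of masking a truth panel
#'
#' Partition of a truth panel into sites retained as genotyped
#' (\code{typed}) and sites hidden from the study sample (\code{masked});
#' masked sites keep their true calls so imputed output can be scored
#' against them.
#'
#' @slot typed,masked \linkS4class{GenotypePanel} partitioning the input.
#' @export
setClass("MaskingResult",
  representation(typed = "GenotypePanel", masked = "GenotypePanel"))

#' SNP-array manifest
#'
#' The set of (chromosome, position) sites genotyped by an array, used to
#' decide which truth-panel sites stay typed under masking.
#'
#' @slot name array label.
#' @slot chrom,pos site coordinates (1-based, unique).
#' @export
setClass("ArrayManifest",
  representation(name = "character", chrom = "character", pos = "integer"))

setValidity("ArrayManifest", function(object) {
  msgs <- character()
  if (length(object@chrom) != length(object@pos))
    msgs <- c(msgs, "chrom and pos must have equal length")
  if (any(object@pos <= 0L)) msgs <- c(msgs, "positions must be positive")
  if (anyDuplicated(paste(object@chrom, object@pos)))
    msgs <- c(msgs, "manifest sites must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ArrayManifest
#' @param chrom,pos site coordinates (1-based).
#' @param name array label.
#' @return An \linkS4class{ArrayManifest}.
#' @export
ArrayManifest <- function(chrom, pos, name = "array") {
  chrom <- rep(as.character(chrom), length.out = length(pos))
  keep <- !duplicated(paste(chrom, pos))
  new("ArrayManifest", name = name,
      chrom = chrom[keep], pos = as.integer(pos)[keep])
}

#' Synthetic-experiment configuration
#'
#' Parameters of the desk-scale emulation of the masking experiment: truth
#' genotypes are drawn under Hardy-Weinberg equilibrium across a MAF
#' spectrum, imputed probability vectors are generated with controllable
#' fidelity, and each target SNP gets one typed proxy SNP with controllable
#' LD.
#'
#' @slot nIndividuals samples per SNP.
#' @slot nSnps number of target SNPs.
#' @slot mafRange range of the log-uniform MAF spectrum (ignored when
#'   \code{mafs} is supplied).
#' @slot mafs optional explicit per-SNP MAFs.
#' @slot fidelity blend weight lambda in [0, 1]: 1 = probability mass fully
#'   on the true genotype, 0 = chance-level draws.
#' @slot concentration Dirichlet sharpness (> 0) of the chance component.
#' @slot imputerMode \code{"BLEND"}, \code{"CHANCE"} (fidelity 0) or
#'   \code{"MAJOR_HOMOZYGOTE"} (all mass on AA).
#' @slot ldFlipRate per-allele flip rate epsilon in [0, 0.5] of the typed
#'   proxy SNP; 0 gives a perfect tag.
#' @slot seed mandatory integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer", nSnps = "integer",
    mafRange = "numeric", mafs = "numeric",
    fidelity = "numeric", concentration = "numeric",
    imputerMode = "character", ldFlipRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nIndividuals < 1L) msgs <- c(msgs, "nIndividuals must be >= 1")
  if (object@nSnps < 1L) msgs <- c(msgs, "nSnps must be >= 1")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msgs <- c(msgs, "mafRange must be increasing within (0, 0.5]")
  if (length(object@mafs) && (any(object@mafs <= 0) || any(object@mafs > 0.5)))
    msgs <- c(msgs, "explicit mafs must lie in (0, 0.5]")
  if (object@fidelity < 0 || object@fidelity > 1)
    msgs <- c(msgs, "fidelity must lie in [0, 1]")
  if (object@concentration <= 0)
    msgs <- c(msgs, "concentration must be > 0")
  if (!object@imputerMode %in% c("BLEND", "CHANCE", "MAJOR_HOMOZYGOTE"))
    msgs <- c(msgs, "imputerMode must be BLEND, CHANCE or MAJOR_HOMOZYGOTE")
  if (object@ldFlipRate < 0 || object@ldFlipRate > 0.5)
    msgs <- c(msgs, "ldFlipRate must lie in [0, 0.5]")
  if (is.na(object@seed)) msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nIndividuals,nSnps problem size.
#' @param seed integer RNG seed (mandatory; all randomness derives from it).
#' @param mafRange log-uniform MAF spectrum bounds, default \code{c(0.001,
#'   0.5)} (rare-heavy, as real site-frequency spectra are).
#' @param mafs optional explicit per-SNP MAFs overriding the spectrum.
#' @param fidelity,concentration,imputerMode,ldFlipRate see
#'   \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nIndividuals, nSnps, seed,
                             mafRange = c(0.001, 0.5), mafs = numeric(0),
                             fidelity = 1, concentration = 20,
                             imputerMode = "BLEND", ldFlipRate = 0.05) {
  if (imputerMode == "CHANCE") fidelity <- 0
  new("SimulationConfig",
      nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
      mafRange = as.numeric(mafRange), mafs = as.numeric(mafs),
      fidelity = as.numeric(fidelity),
      concentration = as.numeric(concentration),
      imputerMode = imputerMode, ldFlipRate = as.numeric(ldFlipRate),
      seed = as.integer(seed))
}
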