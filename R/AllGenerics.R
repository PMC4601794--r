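#' @name accessors
#' @title Accessors for panel objects
#'
#' @description Slot access for \linkS4class{GenotypePanel} and
#' \linkS4class{ImputedPanel}: SNP identifiers, coordinates, sample
#' identifiers, genotype calls, probability matrices, counts.
#'
#' @param x a panel object.
#' @return The corresponding slot content.
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("probabilityMatrices", function(x)
  standardGeneric("probabilityMatrices"))
#' @rdname accessors
#' @export
setGeneric("programScores", function(x) standardGeneric("programScores"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @param i index (integer, logical or SNP id) selecting SNPs.
#' @export
setGeneric("subsetSnps", function(x, i) standardGeneric("subsetSnps"))

#' @rdname accessors
setMethod("snpIds", "GenotypePanel", function(x) x@snpId)
#' @rdname accessors
setMethod("snpIds", "ImputedPanel", function(x) x@snpId)
#' @rdname accessors
setMethod("chromosomes", "GenotypePanel", function(x) x@chrom)
#' @rdname accessors
setMethod("chromosomes", "ImputedPanel", function(x) x@chrom)
#' @rdname accessors
setMethod("positions", "GenotypePanel", function(x) x@pos)
#' @rdname accessors
setMethod("positions", "ImputedPanel", function(x) x@pos)
#' @rdname accessors
setMethod("sampleIds", "GenotypePanel", function(x) x@sampleIds)
#' @rdname accessors
setMethod("sampleIds", "ImputedPanel", function(x) x@sampleIds)
#' @rdname accessors
setMethod("genotypeCalls", "GenotypePanel", function(x) x@calls)
#' @rdname accessors
setMethod("probabilityMatrices", "ImputedPanel", function(x) x@probs)
#' @rdname accessors
setMethod("programScores", "ImputedPanel", function(x) x@programScores)
#' @rdname accessors
setMethod("nSnps", "GenotypePanel", function(x) length(x@snpId))
#' @rdname accessors
setMethod("nSnps", "ImputedPanel", function(x) length(x@snpId))
#' @rdname accessors
setMethod("nSamples", "GenotypePanel", function(x) length(x@sampleIds))
#' @rdname accessors
setMethod("nSamples", "ImputedPanel", function(x) length(x@sampleIds))

.resolveIndex <- function(x, i) {
  if (is.character(i)) i <- match(i, x@snpId)
  if (anyNA(i)) stop("unknown SNP selection")
  i
}

#' @rdname accessors
setMethod("subsetSnps", "GenotypePanel", function(x, i) {
  i <- .resolveIndex(x, i)
  new("GenotypePanel", chrom = x@chrom[i], pos = x@pos[i],
      snpId = x@snpId[i], ref = x@ref[i], alt = x@alt[i],
      calls = x@calls[i, , drop = FALSE], sampleIds = x@sampleIds)
})

#' @rdname accessors
setMethod("subsetSnps", "ImputedPanel", function(x, i) {
  i <- .resolveIndex(x, i)
  new("ImputedPanel", chrom = x@chrom[i], pos = x@pos[i],
      snpId = x@snpId[i], alleleA = x@alleleA[i], alleleB = x@alleleB[i],
      probs = x@probs[i], sampleIds = x@sampleIds, dialect = x@dialect,
      programScores = x@programScores[i])
})

## Reorder/subset samples; used when intersecting truth and imputed samples.
setGeneric("subsetSamples", function(x, ids) standardGeneric("subsetSamples"))

setMethod("subsetSamples", "GenotypePanel", function(x, ids) {
  j <- match(ids, x@sampleIds)
  if (anyNA(j)) stop("unknown sample ids")
  new("GenotypePanel", chrom = x@chrom, pos = x@pos, snpId = x@snpId,
      ref = x@ref, alt = x@alt, calls = x@calls[, j, drop = FALSE],
      sampleIds = x@sampleIds[j])
})

setMethod("subsetSamples", "ImputedPanel", function(x, ids) {
  j <- match(ids, x@sampleIds)
  if (anyNA(j)) stop("unknown sample ids")
  new("ImputedPanel", chrom = x@chrom, pos = x@pos, snpId = x@snpId,
      alleleA = x@alleleA, alleleB = x@alleleB,
      probs = lapply(x@probs, function(p) p[j, , drop = FALSE]),
      sampleIds = x@sampleIds[j], dialect = x@dialect,
      programScores = x@programScores)
})

#' @export
setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nSnps(object), "SNPs x", nSamples(object),
      "samples\n")
  if (nSnps(object)) {
    cat("  chrom:", paste(unique(object@chrom), collapse = ", "), "\n")
    cat("  pos range:", min(object@pos), "-", max(object@pos), "\n")
    cat("  missing calls:", sum(is.na(object@calls)), "\n")
  }
})

#' @export
setMethod("show", "ImputedPanel", function(object) {
  cat("ImputedPanel (", object@dialect, "): ", nSnps(object), " SNPs x ",
      nSamples(object), " samples\n", sep = "")
  if (any(!is.na(object@programScores)))
    cat("  program scores present for", sum(!is.na(object@programScores)),
        "SNPs\n")
})

#' @export
setMethod("show", "ProbabilityTable", function(object) {
  cat("ProbabilityTable (N =", object@nUsed, ")\n")
  m <- round(object@cells, 4)
  dimnames(m) <- list(imputed = c("AA", "AB", "BB"),
                      actual = c("AA", "AB", "BB"))
  print(m)
})

#' @export
setMethod("show", "MaskingResult", function(object) {
  cat("MaskingResult:", nSnps(object@typed), "typed,",
      nSnps(object@masked), "masked sites\n")
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSnps, "SNPs x", object@nIndividuals,
      "individuals;", object@imputerMode,
      sprintf("(fidelity %.2f, concentration %.1f, flip rate %.2f, seed %d)\n",
              object@fidelity, object@concentration, object@ldFlipRate,
              object@seed))
})

#' @rdname accessors
#' @export
setGeneric("typedSites", function(x) standardGeneric("typedSites"))
#' @rdname accessors
#' @export
setGeneric("maskedSites", function(x) standardGeneric("maskedSites"))
#' @rdname accessors
setMethod("typedSites", "MaskingResult", function(x) x@typed)
#' @rdname accessors
setMethod("maskedSites", "MaskingResult", function(x) x@masked)
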