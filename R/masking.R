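## Masking a truth panel: hide genotypes at non-array sites (or at a random
## fraction of sites) so imputed output can be scored against withheld truth.
## In the emulated experiment the reference panel doubles as the study
## sample; the functions here simply partition whatever panel they are given.

#' Mask a truth panel to an array manifest
#'
#' A panel site stays typed iff its (chromosome, position) appears in the
#' manifest; every other site is masked but keeps its true calls for later
#' comparison.  Matching is by genomic position only (the panel and manifest
#' must share a genome build and chromosome naming).  An empty intersection
#' raises a warning and returns an all-masked result.
#'
#' @param panel a \linkS4class{GenotypePanel} of true genotypes.
#' @param manifest an \linkS4class{ArrayManifest}.
#' @return A \linkS4class{MaskingResult}.
#' @export
maskToArray <- function(panel, manifest) {
  stopifnot(is(panel, "GenotypePanel"), is(manifest, "ArrayManifest"))
  key <- paste(chromosomes(panel), positions(panel))
  typed <- key %in% paste(manifest@chrom, manifest@pos)
  if (!any(typed))
    warning("manifest '", manifest@name,
            "' shares no positions with the panel; masking every site")
  new("MaskingResult",
      typed = subsetSnps(panel, which(typed)),
      masked = subsetSnps(panel, which(!typed)))
}

#' Mask a random fraction of sites
#'
#' Masks exactly \code{round(fraction * M)} of the M panel sites, chosen
#' uniformly without replacement under the given seed; the remainder stay
#' typed.  Reproducible for a fixed seed and side-effect free on the global
#' RNG state.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param fraction proportion of sites to mask, in [0, 1].
#' @param seed integer RNG seed.
#' @return A \linkS4class{MaskingResult}.
#' @export
maskRandomFraction <- function(panel, fraction, seed) {
  stopifnot(is(panel, "GenotypePanel"))
  if (is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  m <- nSnps(panel)
  nMask <- round(fraction * m)
  masked <- withr::with_seed(as.integer(seed),
                             sort(sample.int(m, nMask)))
  typed <- setdiff(seq_len(m), masked)
  new("MaskingResult",
      typed = subsetSnps(panel, typed),
      masked = subsetSnps(panel, masked))
}
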