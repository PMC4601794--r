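## End-to-end orchestration: mask -> read imputed output -> per-SNP
## statistics -> MAF/LD bins -> discrepancy tables.  `assessPanel` is the
## in-memory engine; `runAccuracyComparison` wraps it with file I/O, region
## semantics and run metadata for shell use.

#' Assess every shared SNP of a truth and an imputed panel
#'
#' Intersects samples (truth-file order), aligns allele orientation, and
#' computes the full per-SNP accuracy record for every imputed SNP with a
#' truth record, annotated with truth MAF, frequency class and, when a typed
#' panel is given, the maximum LD r-squared against it.  Monomorphic SNPs
#' are flagged and kept in the returned table (callers filter on the flag);
#' their chance-corrected score is NA.
#'
#' @param truth \linkS4class{GenotypePanel} of withheld true genotypes.
#' @param imputed \linkS4class{ImputedPanel} of genotype probabilities.
#' @param typed optional \linkS4class{GenotypePanel} of typed SNPs for LD
#'   annotation.
#' @param ldWindow optional +/- bp window for the LD partner search (default:
#'   all typed SNPs on the same chromosome).
#' @return List: \code{records} (per-SNP data.frame with coordinates,
#'   \code{maf}, \code{frequency_class}, \code{max_r2_ld} and the accuracy
#'   statistics), \code{counts} (stage log: samples shared, SNPs matched /
#'   flipped / excluded, monomorphic).
#' @export
assessPanel <- function(truth, imputed, typed = NULL, ldWindow = NULL) {
  stopifnot(is(truth, "GenotypePanel"), is(imputed, "ImputedPanel"))
  shared <- intersect(sampleIds(truth), sampleIds(imputed))
  if (!length(shared)) stop("no overlapping samples")
  truth <- subsetSamples(truth, shared)
  imputed <- subsetSamples(imputed, shared)
  if (!is.null(typed)) {
    missing <- setdiff(shared, sampleIds(typed))
    if (length(missing)) stop("typed panel lacks shared samples")
    typed <- subsetSamples(typed, shared)
  }
  al <- alignAlleles(imputed, truth)
  imputed <- al$imputed
  rows <- vector("list", nSnps(imputed))
  for (i in seq_len(nSnps(imputed))) {
    tIdx <- al$truthIdx[i]
    calls <- genotypeCalls(truth)[tIdx, ]
    rec <- assessSnp(imputed@probs[[i]], calls, snpId = snpIds(imputed)[i])
    rec$chrom <- chromosomes(imputed)[i]
    rec$pos <- positions(imputed)[i]
    rec$frequency_class <- frequencyClass(rec$maf)
    if (!is.null(typed)) {
      r2 <- maxR2Ld(calls, typed, targetPos = rec$pos,
                    targetChrom = rec$chrom, window = ldWindow)
      if (!is.null(attr(r2, "flag")))
        rec$flags <- .collapseFlags(c(strsplit(rec$flags, ";")[[1]],
                                      attr(r2, "flag")))
      rec$max_r2_ld <- as.numeric(r2)
    } else {
      rec$max_r2_ld <- NA_real_
    }
    rows[[i]] <- rec
  }
  records <- do.call(rbind, rows)
  if (is.null(records)) records <- .emptyRecords()
  cols <- c("snp_id", "chrom", "pos", "maf", "frequency_class", "max_r2_ld",
            "n_used", "concordance", "chance_agreement", "iqs", "r2",
            "beagle_r2", "impute2_info", "flags")
  records <- records[, cols]
  counts <- c(list(samples_shared = length(shared)), al$counts,
              list(monomorphic = sum(grepl(FLAG_MONOMORPHIC,
                                           records$flags))))
  list(records = records, counts = counts)
}

.emptyRecords <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = integer(),
             maf = numeric(), frequency_class = character(),
             max_r2_ld = numeric(), n_used = integer(),
             concordance = numeric(), chance_agreement = numeric(),
             iqs = numeric(), r2 = numeric(), beagle_r2 = numeric(),
             impute2_info = numeric(), flags = character(),
             stringsAsFactors = FALSE)
}

#' Per-SNP discrepancies between IQS and the other statistics
#'
#' Subtracts each companion statistic from the chance-corrected score for
#' every SNP: columns \code{iqs_minus_r2}, \code{iqs_minus_concordance},
#' \code{iqs_minus_beagle_r2}, \code{iqs_minus_info}.  A difference is NA
#' whenever either member of the pair is undefined.  By construction
#' \code{iqs_minus_concordance <= 0} wherever defined.
#'
#' @param records per-SNP accuracy data.frame.
#' @return data.frame keyed by \code{snp_id}.
#' @export
computeDiscrepancies <- function(records) {
  data.frame(
    snp_id = records$snp_id,
    iqs_minus_r2 = records$iqs - records$r2,
    iqs_minus_concordance = records$iqs - records$concordance,
    iqs_minus_beagle_r2 = records$iqs - records$beagle_r2,
    iqs_minus_info = records$iqs - records$impute2_info,
    stringsAsFactors = FALSE)
}

#' Build a run configuration
#'
#' @param truth path to the truth VCF.
#' @param imputed path to the imputed probabilities.
#' @param dialect imputed dialect (\code{VCF_GP}, \code{IMPUTE2_GEN},
#'   \code{BEAGLE_GPROBS}).
#' @param outDir output directory.
#' @param manifest optional array-manifest path (masking by array).
#' @param maskFraction optional random masking fraction (exclusive with
#'   \code{manifest}).
#' @param seed RNG seed for random masking.
#' @param region optional reporting region "chrom:start-end" (1-based
#'   inclusive).
#' @param buffer flanking buffer in bp excluded from reporting at each side
#'   of the region.
#' @param bufferLd logical; when TRUE (default) buffer-region typed SNPs
#'   remain eligible as LD partners even though they are not reported.
#' @param ldWindow optional +/- bp LD search window.
#' @param statistics statistic columns to bin-summarize.
#' @param chrom chromosome label for IMPUTE2 input.
#' @return A validated list of class \code{RunConfig}.
#' @export
runConfig <- function(truth, imputed, dialect, outDir,
                      manifest = NULL, maskFraction = NULL, seed = 1L,
                      region = NULL, buffer = 0L, bufferLd = TRUE,
                      ldWindow = NULL,
                      statistics = c("iqs", "r2", "concordance",
                                     "beagle_r2", "impute2_info"),
                      chrom = "0") {
  if (!is.null(manifest) && !is.null(maskFraction))
    stop("select exactly one masking mode: manifest or maskFraction")
  if (!is.null(region) &&
      !grepl("^[^:]+:[0-9]+-[0-9]+$", region))
    stop("region must be chrom:start-end")
  structure(list(truth = truth, imputed = imputed, dialect = dialect,
                 outDir = outDir, manifest = manifest,
                 maskFraction = maskFraction, seed = as.integer(seed),
                 region = region, buffer = as.integer(buffer),
                 bufferLd = isTRUE(bufferLd), ldWindow = ldWindow,
                 statistics = statistics, chrom = chrom),
            class = "RunConfig")
}

#' Read a run configuration from a YAML key-value file
#'
#' Keys mirror the arguments of \code{\link{runConfig}}.
#'
#' @param path YAML file.
#' @return A \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

.parseRegion <- function(region) {
  chrom <- sub(":.*", "", region)
  rng <- strsplit(sub(".*:", "", region), "-")[[1]]
  list(chrom = chrom, start = as.integer(rng[1]), end = as.integer(rng[2]))
}

#' Run the end-to-end accuracy comparison
#'
#' Reads the truth VCF, partitions it into typed and masked sites (array
#' manifest or random fraction; when neither is given every truth site is
#' treated as masked and LD annotation is skipped), reads the imputed
#' probabilities, intersects samples, scores every masked polymorphic SNP,
#' summarizes each requested statistic in 0.01 bins on the MAF axis (and the
#' max LD r-squared axis when typed sites exist), and writes the per-SNP
#' table, bin summaries, discrepancy table, a sidecar exclusion list of
#' monomorphic/flagged SNPs, and a JSON run-metadata file with the stage
#' counts.  Reporting is restricted to the configured region minus its
#' buffers; buffer typed SNPs stay eligible as LD partners unless
#' \code{bufferLd} is FALSE.
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}} or
#'   \code{\link{readRunConfig}}.
#' @return Invisibly, a list with \code{records}, \code{summaries},
#'   \code{discrepancies}, \code{counts}, \code{files}.
#' @export
runAccuracyComparison <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  truth <- readTruthVcf(config$truth)
  counts <- list(truth_snps = nSnps(truth),
                 truth_skipped = attr(truth, "skipped") %||% 0L)

  if (!is.null(config$manifest)) {
    mask <- maskToArray(truth, readManifest(config$manifest))
  } else if (!is.null(config$maskFraction)) {
    mask <- maskRandomFraction(truth, config$maskFraction, config$seed)
  } else {
    mask <- new("MaskingResult",
                typed = subsetSnps(truth, integer(0)),
                masked = truth)
  }
  typed <- if (nSnps(typedSites(mask))) typedSites(mask) else NULL
  counts$typed_sites <- nSnps(typedSites(mask))
  counts$masked_sites <- nSnps(maskedSites(mask))

  imputed <- readImputedProbabilities(config$imputed, config$dialect,
                                      chrom = config$chrom)
  counts$imputed_snps <- nSnps(imputed)
  counts$imputed_rejected <- attr(imputed, "rejected") %||% 0L

  ## LD search may keep buffer partners; reporting never does.
  ldPanel <- typed
  if (!is.null(config$region) && !is.null(typed) && !config$bufferLd) {
    r <- .parseRegion(config$region)
    keep <- chromosomes(typed) == r$chrom &
      positions(typed) >= r$start + config$buffer &
      positions(typed) <= r$end - config$buffer
    ldPanel <- if (any(keep)) subsetSnps(typed, which(keep)) else NULL
  }

  res <- assessPanel(maskedSites(mask), imputed, typed = ldPanel,
                     ldWindow = config$ldWindow)
  records <- res$records
  counts <- c(counts, res$counts)

  if (!is.null(config$region)) {
    r <- .parseRegion(config$region)
    inRegion <- records$chrom == r$chrom &
      records$pos >= r$start + config$buffer &
      records$pos <= r$end - config$buffer
    counts$outside_region <- sum(!inRegion)
    records <- records[inRegion, , drop = FALSE]
  }

  poly <- !grepl(FLAG_MONOMORPHIC, records$flags)
  excluded <- records[!poly, , drop = FALSE]
  records <- records[poly, , drop = FALSE]
  counts$reported <- nrow(records)
  if (!nrow(records))
    stop("no polymorphic masked SNPs to report")

  axes <- if (is.null(typed)) "maf" else c("maf", "max_r2_ld")
  summaries <- do.call(rbind, lapply(config$statistics, function(s)
    do.call(rbind, lapply(axes, function(ax) {
      b <- binSummarize(records, axis = ax, statistic = s)
      cbind(statistic = s, b)
    }))))

  discrepancies <- computeDiscrepancies(records)

  files <- writeAccuracyTables(records, summaries, discrepancies,
                               config$outDir)
  if (nrow(excluded)) {
    files["excluded"] <- file.path(config$outDir, "excluded_snps.tsv")
    .writeTsv(excluded, files[["excluded"]])
  }
  files["metadata"] <- file.path(config$outDir, "run_metadata.json")
  meta <- list(package = "ImputeAccuracy",
               version = as.character(utils::packageVersion("ImputeAccuracy")),
               seed = config$seed, dialect = config$dialect,
               region = config$region, counts = counts)
  jsonlite::write_json(meta, files[["metadata"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(records = records, summaries = summaries,
                 discrepancies = discrepancies, counts = counts,
                 files = files))
}
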