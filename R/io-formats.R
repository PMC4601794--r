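## Readers and writers for the formats the pipeline touches: VCF truth calls
## (via vcfR), imputed genotype probabilities in VCF GP / IMPUTE2 .gen /
## BEAGLE .gprobs dialects, array manifests (TSV or BED), and the TSV output
## tables.  All text readers are gzip-transparent.  Coordinates are 1-based
## internally; BED input is converted on load.

.openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.readTable <- function(path, header = FALSE, sep = "") {
  con <- .openText(path)
  on.exit(close(con))
  utils::read.table(con, header = header, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a truth genotype panel from VCF
#'
#' Reads GT calls from a VCF (plain or gzipped), keeping biallelic SNP
#' records only: multiallelic sites and indels are skipped with a logged
#' count (returned as the \code{skipped} attribute).  "0/0" maps to 0,
#' "0/1"/"1/0" to 1, "1/1" to 2 and "./." to \code{NA}; phased separators
#' are equivalent.
#'
#' @param path VCF file with a GT FORMAT field.
#' @return A \linkS4class{GenotypePanel}; attribute \code{skipped} counts
#'   non-SNP/multiallelic records dropped.
#' @export
readTruthVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) > 0 && !grepl("GT", vcf@gt[1, "FORMAT"]))
    stop("VCF has no GT field")
  fix <- vcf@fix
  snp <- grepl("^[ACGT]$", fix[, "REF"]) & grepl("^[ACGT]$", fix[, "ALT"])
  nSkipped <- sum(!snp)
  if (nSkipped)
    message("readTruthVcf: skipped ", nSkipped,
            " non-SNP/multiallelic records")
  vcf <- vcf[snp, ]
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- .gtToCalls(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  panel <- GenotypePanel(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    snpId = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
    calls = calls, sampleIds = colnames(gt))
  attr(panel, "skipped") <- nSkipped
  panel
}

.gtToCalls <- function(gt) {
  g <- gsub("\\|", "/", gt)
  out <- matrix(NA_integer_, nrow(gt), ncol(gt))
  out[g == "0/0"] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g == "1/1"] <- 2L
  out
}

#' Read imputed genotype probabilities
#'
#' Normalizes the three probability dialects to an
#' \linkS4class{ImputedPanel}: per-SNP N x 3 matrices in (AA, AB, BB) order
#' where A is the first/reference allele of the record.  Rows whose sum is
#' within 1e-4 of 1 are renormalized; a SNP containing a row further out is
#' rejected with a logged reason.
#'
#' Dialects: \code{VCF_GP} (comma-separated GP triplets, hom-ref/het/hom-alt
#' order), \code{IMPUTE2_GEN} (five leading columns snp_id, rs_id, pos,
#' alleleA, alleleB, then per-sample AA AB BB triplets; the chromosome is
#' not in the file and is taken from \code{chrom}), \code{BEAGLE_GPROBS}
#' (header marker/alleleA/alleleB plus sample ids in triplicate; markers of
#' the form chr:pos are parsed into coordinates).
#'
#' @param path input file (gzip-transparent for the text dialects).
#' @param dialect one of \code{"VCF_GP"}, \code{"IMPUTE2_GEN"},
#'   \code{"BEAGLE_GPROBS"}.
#' @param chrom chromosome label for IMPUTE2 input (not stored in .gen).
#' @param sampleIds sample names for IMPUTE2 input (defaults to S001...).
#' @return An \linkS4class{ImputedPanel}; attribute \code{rejected} counts
#'   SNPs dropped by the row-sum rule.
#' @export
readImputedProbabilities <- function(path,
                                     dialect = c("VCF_GP", "IMPUTE2_GEN",
                                                 "BEAGLE_GPROBS"),
                                     chrom = "0", sampleIds = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         VCF_GP = .readVcfGp(path),
         IMPUTE2_GEN = .readImpute2Gen(path, chrom, sampleIds),
         BEAGLE_GPROBS = .readBeagleGprobs(path))
}

.buildImputedPanel <- function(chrom, pos, snpId, alleleA, alleleB,
                               probRows, sampleIds, dialect) {
  ## probRows: list of N x 3 raw matrices; apply the row-sum rule per SNP.
  ok <- vapply(probRows, function(p) {
    all(is.finite(p)) && all(p >= -ROW_SUM_TOL) &&
      all(abs(rowSums(p) - 1) <= ROW_SUM_TOL)
  }, logical(1))
  if (any(!ok))
    message("readImputedProbabilities: rejected ", sum(!ok),
            " SNPs with probability rows outside the row-sum tolerance")
  panel <- ImputedPanel(
    chrom = chrom[ok], pos = pos[ok], snpId = snpId[ok],
    alleleA = alleleA[ok], alleleB = alleleB[ok],
    probs = probRows[ok], sampleIds = sampleIds, dialect = dialect)
  attr(panel, "rejected") <- sum(!ok)
  panel
}

.readVcfGp <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  snp <- grepl("^[ACGT]$", fix[, "REF"]) & grepl("^[ACGT]$", fix[, "ALT"])
  vcf <- vcf[snp, ]
  fix <- vcf@fix
  gp <- vcfR::extract.gt(vcf, element = "GP")
  if (all(is.na(gp))) stop("VCF has no GP field")
  probRows <- lapply(seq_len(nrow(gp)), function(i) {
    vals <- strsplit(gp[i, ], ",")
    if (any(lengths(vals) != 3L))
      stop("GP triplet malformed at record ", i)
    matrix(as.numeric(unlist(vals)), ncol = 3L, byrow = TRUE)
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  .buildImputedPanel(fix[, "CHROM"], as.integer(fix[, "POS"]), ids,
                     fix[, "REF"], fix[, "ALT"], probRows,
                     colnames(gp), "VCF_GP")
}

.readImpute2Gen <- function(path, chrom, sampleIds) {
  tab <- .readTable(path, header = FALSE)
  if (ncol(tab) < 8L || (ncol(tab) - 5L) %% 3L != 0L)
    stop("IMPUTE2 .gen: probability columns not a multiple of 3")
  n <- (ncol(tab) - 5L) / 3L
  if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(n))
  if (length(sampleIds) != n)
    stop("IMPUTE2 .gen: ", n, " samples in file, ", length(sampleIds),
         " sample ids given")
  probRows <- lapply(seq_len(nrow(tab)), function(i)
    matrix(as.numeric(tab[i, -(1:5)]), ncol = 3L, byrow = TRUE))
  .buildImputedPanel(rep(chrom, nrow(tab)), as.integer(tab[[3]]),
                     as.character(tab[[2]]), as.character(tab[[4]]),
                     as.character(tab[[5]]), probRows, sampleIds,
                     "IMPUTE2_GEN")
}

.readBeagleGprobs <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) stop("empty .gprobs file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if ((length(hdr) - 3L) %% 3L != 0L)
    stop("BEAGLE .gprobs: sample columns not a multiple of 3")
  n <- (length(hdr) - 3L) / 3L
  sampleIds <- hdr[3L + 3L * (seq_len(n) - 1L) + 1L]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  marker <- vapply(body, `[`, "", 1L)
  alleleA <- vapply(body, `[`, "", 2L)
  alleleB <- vapply(body, `[`, "", 3L)
  probRows <- lapply(body, function(x)
    matrix(as.numeric(x[-(1:3)]), ncol = 3L, byrow = TRUE))
  hasPos <- grepl("^[^:]+:[0-9]+$", marker)
  chrom <- ifelse(hasPos, sub(":.*", "", marker), "0")
  pos <- ifelse(hasPos, as.integer(sub(".*:", "", marker)), NA_integer_)
  .buildImputedPanel(chrom, pos, marker, alleleA, alleleB, probRows,
                     sampleIds, "BEAGLE_GPROBS")
}

#' Read an externally reported per-SNP accuracy score
#'
#' Parses the accuracy column the imputation program wrote alongside its
#' probabilities: the \code{info} column of an IMPUTE2 info table (header
#' required) or the two-column BEAGLE .r2 file (marker, r2, no header).
#'
#' @param path score file.
#' @param dialect \code{"IMPUTE2_INFO"} or \code{"BEAGLE_R2"}.
#' @return Named numeric vector of scores keyed by SNP/marker id.
#' @export
readProgramScores <- function(path, dialect = c("IMPUTE2_INFO", "BEAGLE_R2")) {
  dialect <- match.arg(dialect)
  if (dialect == "IMPUTE2_INFO") {
    tab <- .readTable(path, header = TRUE)
    idCol <- intersect(c("rs_id", "snp_id", "rsid"), names(tab))[1]
    if (is.na(idCol) || !"info" %in% names(tab))
      stop("IMPUTE2 info table must have an id column and an 'info' column")
    setNames(as.numeric(tab[["info"]]), as.character(tab[[idCol]]))
  } else {
    tab <- .readTable(path, header = FALSE)
    setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  }
}

#' Attach program scores to an imputed panel
#'
#' @param imputed an \linkS4class{ImputedPanel}.
#' @param scores named numeric vector from \code{\link{readProgramScores}}.
#' @return The panel with \code{programScores} filled where ids match.
#' @export
attachProgramScores <- function(imputed, scores) {
  stopifnot(is(imputed, "ImputedPanel"))
  imputed@programScores <- as.numeric(scores[snpIds(imputed)])
  validObject(imputed)
  imputed
}

#' Read an array manifest
#'
#' TSV manifests are two columns (chrom, 1-based pos) with an optional
#' header; BED manifests are 0-based half-open and each row is converted to
#' the 1-based site \code{start + 1} (site-level BED, one position per row).
#'
#' @param path manifest file.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"bed"}.
#' @param name array label.
#' @return An \linkS4class{ArrayManifest}.
#' @export
readManifest <- function(path, format = c("auto", "tsv", "bed"),
                         name = basename(path)) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "tsv"
  if (format == "bed") {
    tab <- .readTable(path, header = FALSE, sep = "\t")
    return(ArrayManifest(chrom = tab[[1]], pos = as.integer(tab[[2]]) + 1L,
                         name = name))
  }
  first <- strsplit(readLines(.firstLineCon <- .openText(path), n = 1L),
                    "\t|\\s+")[[1]]
  close(.firstLineCon)
  header <- length(first) >= 2L && is.na(suppressWarnings(as.integer(first[2])))
  tab <- .readTable(path, header = header)
  ArrayManifest(chrom = tab[[1]], pos = as.integer(tab[[2]]), name = name)
}

#' Write a genotype panel as VCF
#'
#' Minimal VCF 4.2 with a GT field; calls 0/1/2 are written as 0/0, 0/1,
#' 1/1 and missing as ./..
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(panel, path) {
  stopifnot(is(panel, "GenotypePanel"))
  gtStr <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nSnps(panel)), function(i) {
    g <- genotypeCalls(panel)[i, ]
    gs <- ifelse(is.na(g), "./.", gtStr[g + 1L])
    paste(c(chromosomes(panel)[i], positions(panel)[i], snpIds(panel)[i],
            panel@ref[i], panel@alt[i], ".", "PASS", ".", "GT", gs),
          collapse = "\t")
  }, "")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(panel)), collapse = "\t"),
    body), path)
  invisible(path)
}

#' Write an imputed panel in one of the probability dialects
#'
#' \code{VCF_GP} writes GT:GP records (best-guess GT, 6-decimal GP);
#' \code{IMPUTE2_GEN} writes the five metadata columns plus triplets;
#' \code{BEAGLE_GPROBS} writes the marker/allele header with chr:pos
#' markers.
#'
#' @param imputed an \linkS4class{ImputedPanel}.
#' @param path output path.
#' @param dialect output dialect.
#' @return \code{path}, invisibly.
#' @export
writeImputedProbabilities <- function(imputed, path,
                                      dialect = c("VCF_GP", "IMPUTE2_GEN",
                                                  "BEAGLE_GPROBS")) {
  stopifnot(is(imputed, "ImputedPanel"))
  dialect <- match.arg(dialect)
  fmt <- function(p) sprintf("%.6f", p)
  m <- nSnps(imputed)
  if (dialect == "VCF_GP") {
    gtStr <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(m), function(i) {
      p <- imputed@probs[[i]]
      z <- max.col(p, ties.method = "first")
      cells <- paste0(gtStr[z], ":",
                      apply(p, 1L, function(r) paste(fmt(r), collapse = ",")))
      paste(c(imputed@chrom[i], imputed@pos[i], imputed@snpId[i],
              imputed@alleleA[i], imputed@alleleB[i], ".", "PASS", ".",
              "GT:GP", cells), collapse = "\t")
    }, "")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste0("##FORMAT=<ID=GP,Number=G,Type=Float,",
             "Description=\"Genotype posterior probabilities\">"),
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", sampleIds(imputed)), collapse = "\t"),
      body), path)
  } else if (dialect == "IMPUTE2_GEN") {
    body <- vapply(seq_len(m), function(i) {
      p <- imputed@probs[[i]]
      paste(c(imputed@snpId[i], imputed@snpId[i], imputed@pos[i],
              imputed@alleleA[i], imputed@alleleB[i],
              fmt(as.vector(t(p)))), collapse = " ")
    }, "")
    writeLines(body, path)
  } else {
    hdr <- paste(c("marker", "alleleA", "alleleB",
                   rep(sampleIds(imputed), each = 3L)), collapse = " ")
    body <- vapply(seq_len(m), function(i) {
      p <- imputed@probs[[i]]
      marker <- paste0(imputed@chrom[i], ":", imputed@pos[i])
      paste(c(marker, imputed@alleleA[i], imputed@alleleB[i],
              fmt(as.vector(t(p)))), collapse = " ")
    }, "")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Align imputed alleles to the truth orientation
#'
#' Matches imputed SNPs to truth sites by (chromosome, position) and checks
#' allele orientation.  When the imputed allele pair equals (REF, ALT) the
#' record is kept as is; when it equals (ALT, REF) and the pair is not
#' strand-ambiguous (A/T or C/G), the probability columns are flipped
#' (AA <-> BB) so the coded allele matches the truth ALT; ambiguous swapped
#' pairs and any other mismatch exclude the SNP.
#'
#' @param imputed an \linkS4class{ImputedPanel}.
#' @param truth a \linkS4class{GenotypePanel} containing the truth records
#'   for (a superset of) the imputed sites.
#' @return List: \code{imputed} (aligned subset, columns flipped where
#'   needed), \code{truthIdx} (row index into \code{truth} per kept SNP),
#'   \code{counts} (matched / flipped / unmatched / excluded_allele /
#'   excluded_ambiguous).
#' @export
alignAlleles <- function(imputed, truth) {
  stopifnot(is(imputed, "ImputedPanel"), is(truth, "GenotypePanel"))
  key <- paste(chromosomes(truth), positions(truth))
  idx <- match(paste(chromosomes(imputed), positions(imputed)), key)
  keep <- logical(nSnps(imputed))
  flip <- logical(nSnps(imputed))
  exAllele <- 0L; exAmb <- 0L
  for (i in seq_len(nSnps(imputed))) {
    j <- idx[i]
    if (is.na(j)) next
    a <- toupper(imputed@alleleA[i]); b <- toupper(imputed@alleleB[i])
    r <- toupper(truth@ref[j]); t <- toupper(truth@alt[j])
    if (a == r && b == t) {
      keep[i] <- TRUE
    } else if (a == t && b == r) {
      if (.isAmbiguousPair(a, b)) exAmb <- exAmb + 1L
      else { keep[i] <- TRUE; flip[i] <- TRUE }
    } else exAllele <- exAllele + 1L
  }
  out <- subsetSnps(imputed, which(keep))
  flipKept <- flip[keep]
  if (any(flipKept)) {
    out@probs[flipKept] <- lapply(out@probs[flipKept],
                                  function(p) p[, 3:1, drop = FALSE])
    tmp <- out@alleleA[flipKept]
    out@alleleA[flipKept] <- out@alleleB[flipKept]
    out@alleleB[flipKept] <- tmp
  }
  if (any(flipKept))
    message("alignAlleles: flipped allele orientation for ", sum(flipKept),
            " SNPs")
  list(imputed = out, truthIdx = idx[keep],
       counts = list(matched = sum(keep), flipped = sum(flipKept),
                     unmatched = sum(is.na(idx)),
                     excluded_allele = exAllele,
                     excluded_ambiguous = exAmb))
}

#' Write the pipeline output tables
#'
#' Writes the per-SNP accuracy table, the bin summaries and the discrepancy
#' table as TSV with \code{NA} for undefined values; rows are ordered by
#' (chromosome, position) where coordinates are present.
#'
#' @param records per-SNP accuracy data.frame.
#' @param summaries bin-summary data.frame (may be NULL).
#' @param discrepancies discrepancy data.frame (may be NULL).
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
writeAccuracyTables <- function(records, summaries = NULL,
                                discrepancies = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (all(c("chrom", "pos") %in% names(records)) && nrow(records))
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
  files <- c(records = file.path(dir, "snp_accuracy.tsv"))
  .writeTsv(records, files[["records"]])
  if (!is.null(summaries)) {
    files["summaries"] <- file.path(dir, "bin_summaries.tsv")
    .writeTsv(summaries, files[["summaries"]])
  }
  if (!is.null(discrepancies)) {
    files["discrepancies"] <- file.path(dir, "discrepancies.tsv")
    .writeTsv(discrepancies, files[["discrepancies"]])
  }
  invisible(files)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
}

#' Read a TSV written by \code{\link{writeAccuracyTables}}
#' @param path TSV path.
#' @return data.frame.
#' @export
readAccuracyTable <- function(path) {
  .readTable(path, header = TRUE, sep = "\t")
}
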