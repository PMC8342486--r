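#' Read a case/control genotype table
#'
#' Reads the package's plain genotype table format: a header row followed by
#' one row per sample, with columns \code{sample_id}, \code{phenotype}
#' (1 = case, 0 = control) and one column per SNV holding genotype codes 0
#' (0/0), 1 (0/1) or 2 (1/1).
#'
#' @param path path to a TSV (default) or CSV file.
#' @param dialect \code{"tsv"} or \code{"csv"}; guessed from the file
#'   extension when omitted.
#' @param dropMissingSamples if \code{TRUE}, rows with missing genotype cells
#'   are removed (with a message); the default is a hard error, since silent
#'   imputation would corrupt the contingency counts.
#' @return A \linkS4class{GenotypeExperiment}.
#' @seealso [writeGenotypeTable()], [readVcfGenotypes()]
#' @export
readGenotypeTable <- function(path, dialect = NULL, dropMissingSamples = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "csv" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "csv"))
  sep <- if (dialect == "csv") "," else "\t"

  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(hdr) < 3L)
    stop("genotype table needs at least sample_id, phenotype and one SNV column")
  snvHdr <- hdr[-(1:2)]
  if (any(!nzchar(trimws(snvHdr))))
    stop("unnamed SNV column in header (position ",
         which(!nzchar(trimws(snvHdr)))[1] + 2L, ")")
  if (anyDuplicated(snvHdr))
    stop("duplicate SNV identifier in header: ",
         snvHdr[duplicated(snvHdr)][1])
  if (!"phenotype" %in% hdr[2])
    stop("second column must be named 'phenotype'")

  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (ncol(dt) != length(hdr))  # trailing empty header cells are dropped by strsplit
    stop("unnamed SNV column in header")
  sampleIds <- as.character(dt[[1]])
  phen <- dt[[2]]
  if (anyNA(phen) || !all(phen %in% c(0, 1)))
    stop("phenotype column must be coded 0 (control) / 1 (case)")
  g <- as.matrix(dt[, -(1:2), drop = FALSE])

  if (anyNA(g)) {
    bad <- which(apply(is.na(g), 1L, any))
    if (!dropMissingSamples) {
      idx <- which(is.na(g), arr.ind = TRUE)[1, ]
      stop("missing genotype at sample '", sampleIds[idx[1]], "', SNV '",
           snvHdr[idx[2]], "'; rerun with dropMissingSamples = TRUE to drop ",
           "affected samples")
    }
    message("dropping ", length(bad), " sample(s) with missing genotypes")
    g <- g[-bad, , drop = FALSE]
    sampleIds <- sampleIds[-bad]
    phen <- phen[-bad]
  }
  badCode <- !(g %in% 0:2)
  if (any(badCode)) {
    idx <- which(matrix(badCode, nrow = nrow(g)), arr.ind = TRUE)[1, ]
    stop("invalid genotype code '", g[idx[1], idx[2]], "' at sample '",
         sampleIds[idx[1]], "', SNV '", snvHdr[idx[2]], "'")
  }

  rownames(g) <- sampleIds
  colnames(g) <- snvHdr
  ge <- GenotypeExperiment(g, phenotype = as.numeric(phen))
  .logCohort(ge)
  ge
}

.logCohort <- function(ge) {
  message(sprintf("loaded %d samples x %d SNVs (%d cases, %d controls)",
                  ncol(ge), nrow(ge), nCases(ge), nControls(ge)))
}

#' Write a GenotypeExperiment as a genotype table
#'
#' Inverse of [readGenotypeTable()]: writes columns \code{sample_id},
#' \code{phenotype} and one column per SNV.
#'
#' @param x a \linkS4class{GenotypeExperiment} or
#'   \linkS4class{SimulatedDataset}.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
writeGenotypeTable <- function(x, path, dialect = c("tsv", "csv")) {
  if (is(x, "SimulatedDataset")) x <- simData(x)
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(sample_id = colnames(x),
                   phenotype = as.integer(phenotype(x) == "case"),
                   t(genotypes(x)), check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bi-allelic genotypes from a VCF plus a phenotype file
#'
#' Loads GT calls from a VCF 4.x file (gzip accepted) and pairs them with a
#' two-column sample-to-phenotype table.  Calls map as 0/0 -> 0, 0/1 or
#' 1/0 -> 1, 1/1 -> 2; phased separators (\code{|}) are treated identically
#' since the statistics are genotype-based, not haplotype-based.  Records
#' must be bi-allelic: split multi-allelic sites beforehand (e.g. with
#' \code{bcftools norm -m-}).
#'
#' @param path VCF path.
#' @param phenotypePath two-column TSV (\code{sample}, \code{phenotype} with
#'   values 0/1); a header line is optional.
#' @param dropMissingSamples as in [readGenotypeTable()]: samples with any
#'   missing GT (\code{./.}) are dropped instead of raising an error.
#' @return A \linkS4class{GenotypeExperiment}; SNV ids come from the VCF ID
#'   column, falling back to \code{CHROM:POS:REF:ALT} where ID is ".".
#' @export
readVcfGenotypes <- function(path, phenotypePath, dropMissingSamples = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  altL <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(altL) > 1))
    stop("multi-allelic record at ",
         as.character(SummarizedExperiment::rowRanges(vcf))[
           which(S4Vectors::elementNROWS(altL) > 1)[1]],
         "; normalize to bi-allelic records first (e.g. bcftools norm -m-)")
  rr <- SummarizedExperiment::rowRanges(vcf)
  vid <- names(rr)
  auto <- paste(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr),
                as.character(VariantAnnotation::ref(vcf)),
                as.character(unlist(altL)), sep = ":")
  noId <- is.na(vid) | vid == "." | !nzchar(vid) | grepl("^[^:]+:[0-9]+_", vid)
  vid[noId] <- auto[noId]

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm %in% "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% "1/1"] <- 2L
  missing <- norm %in% c("./.", ".", "./0", "0/.")
  unknown <- is.na(code) & !missing
  if (any(unknown))
    stop("unsupported GT value '", gt[which(unknown)[1]],
         "' (only bi-allelic 0/1 calls are handled)")

  phen <- .readPhenotypeFile(phenotypePath)
  vcfSamples <- colnames(gt)
  absent <- setdiff(vcfSamples, names(phen))
  if (length(absent))
    stop("sample(s) in VCF absent from phenotype file: ",
         paste(head(absent, 5), collapse = ", "))
  extra <- setdiff(names(phen), vcfSamples)
  if (length(extra))
    message(length(extra), " phenotype entries without VCF sample ignored")
  phen <- phen[vcfSamples]

  g <- t(code)  # samples x SNVs
  colnames(g) <- vid
  if (anyNA(g)) {
    bad <- which(apply(is.na(g), 1L, any))
    if (!dropMissingSamples) {
      idx <- which(is.na(g), arr.ind = TRUE)[1, ]
      stop("missing GT for sample '", rownames(g)[idx[1]], "' at '",
           vid[idx[2]], "'; rerun with dropMissingSamples = TRUE")
    }
    message("dropping ", length(bad), " sample(s) with missing GT")
    g <- g[-bad, , drop = FALSE]
    phen <- phen[-bad]
  }
  ge <- GenotypeExperiment(g, phenotype = unname(phen))
  .logCohort(ge)
  ge
}

.readPhenotypeFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(df) < 2) stop("phenotype file needs two columns: sample, phenotype")
  ph <- df[[2]]
  if (anyNA(ph) || !all(ph %in% c(0, 1)))
    stop("phenotype values must be 0 (control) / 1 (case)")
  stats::setNames(as.numeric(ph), as.character(df[[1]]))
}

#' Encode a cohort pair into the bitwise representation
#'
#' Splits the samples by phenotype and packs each cohort's genotypes into
#' byte vectors (one byte per sample per SNV, genotype in the low two bits),
#' together with copies pre-shifted by 2, 4 and 6 bits.  Sample order within
#' each cohort preserves the input order.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @return Named list with \code{case} and \code{control}
#'   \linkS4class{EncodedCohort} objects.
#' @examples
#' enc <- encodeCohorts(demoPairDataset())
#' enc$case
#' @export
encodeCohorts <- function(x) {
  stopifnot(is(x, "GenotypeExperiment"))
  if (nCases(x) == 0L || nControls(x) == 0L)
    stop("both cohorts must be non-empty")
  g <- genotypes(x)
  list(case = .encodeOne(g[, phenotype(x) == "case", drop = FALSE], "case"),
       control = .encodeOne(g[, phenotype(x) == "control", drop = FALSE],
                            "control"))
}

.encodeOne <- function(gSnvBySample, cohort) {
  m <- t(gSnvBySample)  # samples x SNVs
  shifts <- lapply(c(0L, 2L, 4L, 6L), function(k) {
    r <- as.raw(bitwShiftL(as.integer(m), k))
    dim(r) <- dim(m)
    dimnames(r) <- dimnames(m)
    r
  })
  names(shifts) <- c("0", "2", "4", "6")
  new("EncodedCohort", cohort = cohort, s = nrow(m),
      snvIds = colnames(m), shifts = shifts)
}

#' Decode an EncodedCohort back to genotype codes
#'
#' @param x an \linkS4class{EncodedCohort}.
#' @return integer matrix, samples x SNVs.
#' @export
decodeCohort <- function(x) {
  stopifnot(is(x, "EncodedCohort"))
  g <- as.integer(x@shifts[["0"]])
  dim(g) <- c(x@s, length(x@snvIds))
  dimnames(g) <- dimnames(x@shifts[["0"]])
  g
}
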