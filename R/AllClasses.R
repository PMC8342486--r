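#' GenotypeExperiment: case/control genotype matrix container
#'
#' A thin \linkS4class{SummarizedExperiment} holding one integer assay
#' \code{"genotype"} with SNVs as rows and samples as columns.  Genotype codes
#' are 0 (0/0), 1 (0/1 heterozygous) and 2 (1/1); no missing values are
#' allowed once constructed.  \code{colData} carries a \code{phenotype} factor
#' with levels \code{control}, \code{case}.
#'
#' @slot .. inherited from SummarizedExperiment; no extra slots.
#' @seealso [GenotypeExperiment()], [genotypes()], [phenotype()]
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is required")
  g <- SummarizedExperiment::assay(object, "genotype")
  if (!is.numeric(g))
    return("genotype assay must be numeric")
  if (anyNA(g))
    return("genotype assay contains missing values")
  if (!all(g %in% 0:2))
    return("genotype codes must be in {0,1,2}")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)) ||
      any(!nzchar(rownames(object))))
    return("SNV identifiers (rownames) must be present, non-empty and unique")
  ph <- SummarizedExperiment::colData(object)$phenotype
  if (is.null(ph))
    return("colData must contain a 'phenotype' column")
  if (!is.factor(ph) || !identical(levels(ph), c("control", "case")))
    return("phenotype must be a factor with levels control, case")
  if (anyNA(ph))
    return("phenotype contains missing values")
  TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param genotypes integer matrix of genotype codes in \code{{0,1,2}} with
#'   samples as rows and SNVs as columns (the layout of the genotype table
#'   file format); row/column names supply sample and SNV identifiers.
#' @param phenotype per-sample phenotype: a 0/1 numeric vector (1 = case), a
#'   logical vector (TRUE = case), or a factor with levels
#'   \code{control}/\code{case}.
#' @param snvIds,sampleIds optional identifier overrides.
#' @return A \linkS4class{GenotypeExperiment}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L, 0L, 2L), nrow = 4,
#'             dimnames = list(paste0("S", 1:4), c("A", "B")))
#' ge <- GenotypeExperiment(g, phenotype = c(1, 1, 0, 0))
#' nCases(ge)
#' @export
GenotypeExperiment <- function(genotypes, phenotype,
                               snvIds = colnames(genotypes),
                               sampleIds = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(snvIds)) snvIds <- paste0("SNV_", seq_len(ncol(genotypes)))
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(genotypes)))
  ph <- .asPhenotypeFactor(phenotype)
  if (length(ph) != nrow(genotypes))
    stop("phenotype length (", length(ph), ") does not match the number of samples (",
         nrow(genotypes), ")")
  storage.mode(genotypes) <- "integer"
  a <- t(genotypes)
  dimnames(a) <- list(snvIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = a),
    colData = S4Vectors::DataFrame(phenotype = ph, row.names = sampleIds))
  new("GenotypeExperiment", se)
}

.asPhenotypeFactor <- function(phenotype) {
  if (is.factor(phenotype)) {
    if (!all(levels(phenotype) %in% c("control", "case")))
      stop("phenotype factor levels must be 'control' and 'case'")
    return(factor(as.character(phenotype), levels = c("control", "case")))
  }
  if (is.logical(phenotype))
    return(factor(ifelse(phenotype, "case", "control"),
                  levels = c("control", "case")))
  if (is.numeric(phenotype)) {
    if (anyNA(phenotype) || !all(phenotype %in% c(0, 1)))
      stop("numeric phenotype must be coded 0 (control) / 1 (case)")
    return(factor(ifelse(phenotype == 1, "case", "control"),
                  levels = c("control", "case")))
  }
  if (is.character(phenotype)) {
    if (!all(phenotype %in% c("control", "case")))
      stop("character phenotype must use 'control'/'case'")
    return(factor(phenotype, levels = c("control", "case")))
  }
  stop("unsupported phenotype representation")
}

#' EncodedCohort: packed 2-bit genotype byte vectors for one cohort
#'
#' One cohort's genotypes packed for the bitwise counting engine: per SNV, a
#' byte per sample holding the 2-bit genotype code (00, 01, 10 for 0/0, 0/1,
#' 1/1), plus pre-shifted copies at 2, 4 and 6 bits so that up to four SNVs
#' can be combined with bitwise OR without shifting at test time.
#'
#' @slot cohort \code{"case"} or \code{"control"}.
#' @slot s number of samples in the cohort.
#' @slot snvIds SNV identifiers (column order of the byte matrices).
#' @slot shifts list of four \code{s x n_snv} raw matrices named
#'   \code{"0","2","4","6"}; matrix \code{k} holds \code{code << k}.
#' @export
setClass("EncodedCohort",
         representation(cohort = "character", s = "integer",
                        snvIds = "character", shifts = "list"))

setValidity("EncodedCohort", function(object) {
  if (!object@cohort %in% c("case", "control"))
    return("cohort must be 'case' or 'control'")
  if (!identical(names(object@shifts), c("0", "2", "4", "6")))
    return("shifts must be named '0','2','4','6'")
  s0 <- object@shifts[["0"]]
  if (!is.raw(s0) || !is.matrix(s0))
    return("shift matrices must be raw matrices")
  if (nrow(s0) != object@s || ncol(s0) != length(object@snvIds))
    return("shift-0 matrix dimensions do not match s / snvIds")
  if (!all(as.integer(s0) %in% 0:2))
    return("shift-0 bytes must be 0x00, 0x01 or 0x02")
  for (k in c(2L, 4L, 6L)) {
    sk <- object@shifts[[as.character(k)]]
    if (!identical(dim(sk), dim(s0)))
      return("shifted matrices must match shift-0 dimensions")
    if (!identical(as.integer(sk), bitwShiftL(as.integer(s0), k)))
      return(sprintf("shift-%d bytes are not shift-0 bytes << %d", k, k))
  }
  TRUE
})

#' ContingencyTable: 3^m x 2 genotype-combination counts
#'
#' Counts of case and control samples per genotype combination of an m-SNV
#' tuple.  Row r (0-based) encodes genotypes g_1..g_m through
#' r = sum g_i * 3^(i-1): the first tuple slot is the fastest-varying digit.
#'
#' @slot m interaction order (1--4).
#' @slot counts integer matrix, \code{3^m} rows x 2 columns
#'   (\code{case}, \code{control}); rownames are genotype labels like
#'   \code{"0/1,0/1"}.
#' @slot snvIds identifiers of the counted tuple, in slot order.
#' @export
setClass("ContingencyTable",
         representation(m = "integer", counts = "matrix",
                        snvIds = "character"))

setValidity("ContingencyTable", function(object) {
  if (object@m < 1L || object@m > 4L) return("order m must be in 1..4")
  if (nrow(object@counts) != 3L^object@m || ncol(object@counts) != 2L)
    return("counts must have 3^m rows and 2 columns")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@snvIds) != object@m) return("snvIds length must equal m")
  TRUE
})

#' BetaCache: dense store of all order-k combined association powers
#'
#' Dense multi-index store of beta for every k-tuple of SNVs, used when
#' computing alpha at order k+1 (the maximum (m-1)-subset beta is subtracted
#' from the tuple's beta).  Storage is a flat numeric vector of length n^k
#' indexed by the sorted 0-based tuple (i_1 < ... < i_k) at position
#' sum i_j * n^(j-1); unused slots hold NA.  Order 0 stores the single value
#' beta of the whole-cohort set.
#'
#' @slot order cached tuple order k (0--3).
#' @slot n number of SNVs.
#' @slot snvIds SNV identifiers.
#' @slot values flat numeric store.
#' @export
setClass("BetaCache",
         representation(order = "integer", n = "integer",
                        snvIds = "character", values = "numeric"))

#' NullDistribution: permutation null of an association statistic
#'
#' Values of alpha or beta for one SNV tuple recomputed under phenotype
#' permutations that preserve the case/control sizes.
#'
#' @slot statistic \code{"alpha"} or \code{"beta"}.
#' @slot snvIds the tuple's SNV identifiers.
#' @slot samples permuted-data statistic values, length \code{nPerm}.
#' @slot nPerm number of permutations.
#' @slot seed integer seed used.
#' @export
setClass("NullDistribution",
         representation(statistic = "character", snvIds = "character",
                        samples = "numeric", nPerm = "integer",
                        seed = "integer"))

setValidity("NullDistribution", function(object) {
  if (!object@statistic %in% c("alpha", "beta"))
    return("statistic must be 'alpha' or 'beta'")
  if (length(object@samples) != object@nPerm)
    return("length(samples) must equal nPerm")
  TRUE
})

#' PenetranceModel: genotype-combination to disease-probability map
#'
#' A GAMETES-style epistasis model: minor-allele frequencies for m interacting
#' SNVs plus a 3^m table of disease probabilities, one per genotype
#' combination (indexed like \linkS4class{ContingencyTable} rows).
#'
#' @slot m number of interacting SNVs.
#' @slot mafs minor-allele frequencies in (0, 0.5].
#' @slot penetrance numeric vector of length 3^m with values in [0, 1].
#' @slot label human-readable model name.
#' @export
setClass("PenetranceModel",
         representation(m = "integer", mafs = "numeric",
                        penetrance = "numeric", label = "character"))

setValidity("PenetranceModel", function(object) {
  if (length(object@mafs) != object@m)
    return("mafs length must equal m")
  if (any(object@mafs <= 0) || any(object@mafs > 0.5))
    return("mafs must lie in (0, 0.5]")
  if (length(object@penetrance) != 3L^object@m)
    return("penetrance must have 3^m entries")
  if (any(object@penetrance < 0) || any(object@penetrance > 1))
    return("penetrance values must lie in [0, 1]")
  TRUE
})

#' SimulatedDataset: genotype data with known planted interactions
#'
#' @slot data the simulated \linkS4class{GenotypeExperiment}.
#' @slot truth list of integer vectors: planted truth tuples as SNV column
#'   indices of \code{data}.
#' @slot seed integer seed the dataset was generated from.
#' @export
setClass("SimulatedDataset",
         representation(data = "GenotypeExperiment", truth = "list",
                        seed = "integer"))
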