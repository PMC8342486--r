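#' Map a combined genotype byte to its contingency-table row
#'
#' In the combined byte for an m-SNV tuple, slot i's genotype occupies bits
#' 2(i-1)..2i-1.  The row index is the little-endian base-3 reading of the
#' genotype digits: r = sum g_i * 3^(i-1).  So with m = 4 the byte
#' \code{0b00010010} (slots 1..4 holding 2, 0, 1, 0) maps to row
#' 2 + 0*3 + 1*9 + 0*27 = 11.
#'
#' @param byteValue integer (0--255) or raw byte.
#' @param m interaction order, 1--4.
#' @return 0-based row index in the 3^m-row table.
#' @export
byteToRow <- function(byteValue, m) {
  m <- .checkOrder(m)
  b <- as.integer(byteValue)
  if (length(b) != 1L || is.na(b) || b < 0L || b > 255L)
    stop("byteValue must be a single value in 0..255")
  fields <- bitwAnd(bitwShiftR(b, 2L * (0:3)), 3L)
  if (any(fields == 3L))
    stop("invalid combined genotype byte")
  if (m < 4L && any(fields[(m + 1L):4L] != 0L))
    stop("invalid combined genotype byte")
  sum(fields[seq_len(m)] * 3L^(seq_len(m) - 1L))
}

.checkOrder <- function(m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > 4L)
    stop("order m must be 1, 2, 3 or 4 (an 8-bit byte holds at most four ",
         "2-bit genotypes)")
  m
}

.resolveTuple <- function(ids, tuple) {
  if (is.character(tuple)) {
    idx <- match(tuple, ids)
    if (anyNA(idx)) stop("unknown SNV id: ", tuple[is.na(idx)][1])
  } else {
    idx <- as.integer(tuple)
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(ids)))
      stop("SNV index out of range")
  }
  if (length(idx) == 0L) stop("empty SNV tuple")
  if (anyDuplicated(idx)) stop("duplicate SNV in tuple")
  .checkOrder(length(idx))
  idx
}

.rowLabels <- function(m) {
  lab <- c("0/0", "0/1", "1/1")
  digits <- as.matrix(expand.grid(rep(list(0:2), m))[, seq_len(m), drop = FALSE])
  apply(digits, 1L, function(d) paste(lab[d + 1L], collapse = ","))
}

.newTable <- function(countsMatrix, m, ids) {
  storage.mode(countsMatrix) <- "integer"
  dimnames(countsMatrix) <- list(.rowLabels(m), c("case", "control"))
  new("ContingencyTable", m = m, counts = countsMatrix, snvIds = ids)
}

#' Count genotype combinations with the 1-Vector bitwise engine
#'
#' Builds the 3^m x 2 contingency table for an m-SNV tuple by OR-combining
#' the tuple's pre-shifted byte vectors (slot j at shift 2(j-1)) into one
#' byte per sample and histogramming the byte values; the 3^m legal byte
#' patterns map onto table rows and every other bin must be empty.
#'
#' @param case,control \linkS4class{EncodedCohort} objects from
#'   [encodeCohorts()].
#' @param tuple m SNV ids or column indices, m in 1..4, no duplicates.
#' @return A \linkS4class{ContingencyTable}.
#' @examples
#' enc <- encodeCohorts(demoPairDataset())
#' countOneVector(enc$case, enc$control, c("A", "B"))
#' @export
countOneVector <- function(case, control, tuple) {
  stopifnot(is(case, "EncodedCohort"), is(control, "EncodedCohort"))
  if (case@cohort != "case" || control@cohort != "control")
    stop("arguments must be the case and control EncodedCohort, in that order")
  if (!identical(case@snvIds, control@snvIds))
    stop("cohorts were encoded over different SNV sets")
  idx <- .resolveTuple(case@snvIds, tuple)
  m <- length(idx)
  cnt <- cpp_count_1v(case@shifts, control@shifts, idx - 1L)
  .newTable(cnt, m, case@snvIds[idx])
}

#' Count genotype combinations with the 3-Vector reference engine
#'
#' Reference implementation of the classic bitwise counting scheme: each SNV
#' becomes three 1-bit-per-sample indicator vectors (one per genotype) packed
#' in 64-bit words; each of the 3^m genotype combinations is counted by
#' AND-ing the m indicators and popcounting.  Results are cell-identical to
#' [countOneVector()].
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param tuple m SNV ids or indices, m in 1..4.
#' @return A \linkS4class{ContingencyTable}.
#' @export
countThreeVector <- function(x, tuple) {
  stopifnot(is(x, "GenotypeExperiment"))
  idx <- .resolveTuple(snvIds(x), tuple)
  g <- genotypes(x)
  isCase <- phenotype(x) == "case"
  gc <- t(g[idx, isCase, drop = FALSE])
  gt <- t(g[idx, !isCase, drop = FALSE])
  cnt <- cpp_count_3v(gc, gt)
  .newTable(cnt, length(idx), snvIds(x)[idx])
}

#' Count genotype combinations by direct per-sample grouping
#'
#' Naive oracle: computes each sample's table row from its genotype codes and
#' tabulates per cohort.  Used to cross-check the bitwise engines.
#'
#' @inheritParams countThreeVector
#' @return A \linkS4class{ContingencyTable}.
#' @export
countNaive <- function(x, tuple) {
  stopifnot(is(x, "GenotypeExperiment"))
  idx <- .resolveTuple(snvIds(x), tuple)
  m <- length(idx)
  g <- genotypes(x)[idx, , drop = FALSE]
  rows <- as.integer(colSums(g * 3^(seq_len(m) - 1L)))
  isCase <- phenotype(x) == "case"
  cnt <- cbind(tabulate(rows[isCase] + 1L, nbins = 3L^m),
               tabulate(rows[!isCase] + 1L, nbins = 3L^m))
  .newTable(cnt, m, snvIds(x)[idx])
}

#' Dump a contingency table as TSV
#'
#' Writes genotype labels (one column per tuple slot) plus case and control
#' counts.
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @param path output path.
#' @export
writeContingencyTable <- function(table, path) {
  stopifnot(is(table, "ContingencyTable"))
  labs <- do.call(rbind, strsplit(rownames(table@counts), ",", fixed = TRUE))
  colnames(labs) <- table@snvIds
  df <- data.frame(labs, case = table@counts[, "case"],
                   control = table@counts[, "control"], check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
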