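#' Gini-based purity of a case/control set
#'
#' For a set holding \code{x} cases and \code{y} controls the purity is
#' \code{(x^2 + y^2) / (x + y)^2}: 0.5 for a perfectly mixed set, 1 for a
#' single-cohort set.  The empty set returns 0 so that it contributes nothing
#' to the weighted average (its weight is 0 anyway).
#'
#' @param x,y non-negative case and control counts (vectorised).
#' @return purity value(s) in \code{[0.5, 1]} (0 for empty sets).
#' @examples
#' purity(10, 10)  # 0.5
#' purity(3, 1)    # 0.625
#' @export
purity <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  t <- x + y
  p <- ifelse(t > 0, (x^2 + y^2) / t^2, 0)
  unname(p)
}

.betaFromCounts <- function(x, y, n) {
  t <- x + y
  nz <- t > 0
  sum((t[nz] / n) * (x[nz]^2 + y[nz]^2) / t[nz]^2)
}

#' Combined association power (beta) of a contingency table
#'
#' The count-weighted mean purity over the table's genotype-combination rows:
#' \deqn{\beta = \sum_i \frac{x_i + y_i}{n} \cdot
#'   \frac{x_i^2 + y_i^2}{(x_i + y_i)^2}}
#' where \eqn{x_i, y_i} are the case/control counts of row i and n the total
#' sample count.  Empty rows contribute 0.  Beta lies in \code{[0.5, 1]} and
#' is monotone non-decreasing when an SNV is added to the tuple.
#'
#' @param table a \linkS4class{ContingencyTable}.
#' @return beta in \code{[0.5, 1]}.
#' @export
betaFromTable <- function(table) {
  stopifnot(is(table, "ContingencyTable"))
  n <- sum(table@counts)
  if (n == 0) stop("empty cohort: all contingency cells are zero")
  .betaFromCounts(table@counts[, "case"], table@counts[, "control"], n)
}

#' Baseline association power of the whole cohort
#'
#' Beta of the 0-SNV "tuple": the purity of the set containing every sample.
#' This is the baseline subtracted when computing alpha for a single SNV.
#'
#' @param x a \linkS4class{GenotypeExperiment}, or a phenotype factor/0-1
#'   vector.
#' @return purity of (n_cases, n_controls).
#' @export
betaZero <- function(x) {
  if (is(x, "GenotypeExperiment")) {
    nc <- nCases(x); nt <- nControls(x)
  } else {
    ph <- .asPhenotypeFactor(x)
    nc <- sum(ph == "case"); nt <- sum(ph == "control")
  }
  if (nc + nt == 0L) stop("empty phenotype")
  purity(nc, nt)
}

#' Interaction effect size (alpha) from beta values
#'
#' \deqn{\alpha_{G^m} = \beta_{G^m} - \max_i \beta_{G^{m-1}_i}} the gain in
#' combined association power attributable only to the full m-tuple.  Only
#' the (m-1)-subsets are needed: their maximum dominates all smaller subsets
#' by the monotonicity of beta.  For m = 1 the single "subset" beta is the
#' whole-cohort baseline [betaZero()].  Tiny negative results (above -1e-12,
#' floating-point noise) are clamped to 0; anything more negative signals a
#' counting bug and raises an error.
#'
#' @param betaM beta of the full m-tuple.
#' @param subsetBetas the m beta values of its (m-1)-subsets (one value,
#'   betaZero, when m = 1).
#' @param m interaction order; defaults to \code{length(subsetBetas)}.
#' @return alpha >= 0.
#' @export
alphaFromBetas <- function(betaM, subsetBetas, m = length(subsetBetas)) {
  m <- .checkOrder(m)
  if (length(subsetBetas) != m)
    stop("need exactly m = ", m, " subset beta values, got ",
         length(subsetBetas))
  a <- betaM - max(subsetBetas)
  if (a < 0) {
    if (a > -1e-12) a <- 0
    else stop("internal consistency error: beta of the tuple is below the ",
              "best subset beta by ", format(-a))
  }
  a
}

#' Precompute all order-k combined association powers
#'
#' Computes beta for every k-tuple of SNVs once and stores the values in a
#' dense multi-index array, so that alpha at order k+1 can look up its
#' (m-1)-subset betas instead of recomputing them for every containing tuple.
#' Order 0 stores the single whole-cohort baseline.
#'
#' @param x a \linkS4class{GenotypeExperiment}, or the list returned by
#'   [encodeCohorts()] (then \code{phenotype} counts are taken from the
#'   cohort sizes).
#' @param order tuple order k in 0..3.
#' @return A \linkS4class{BetaCache}.
#' @export
buildBetaCache <- function(x, order) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 0L || order > 3L)
    stop("cache order must be in 0..3")
  enc <- if (is(x, "GenotypeExperiment")) encodeCohorts(x) else x
  stopifnot(is(enc$case, "EncodedCohort"), is(enc$control, "EncodedCohort"))
  n <- length(enc$case@snvIds)
  if (order > n) stop("cache order exceeds the number of SNVs")
  b0 <- purity(enc$case@s, enc$control@s)
  if (order == 0L)
    return(new("BetaCache", order = 0L, n = as.integer(n),
               snvIds = enc$case@snvIds, values = b0))
  if (n^order > 2^27)
    stop("dense beta cache would exceed 2^27 entries; reduce the SNV set")
  res <- cpp_search(enc$case@shifts, enc$control@shifts, n,
                    startCombo = 0:(order - 1L),
                    count = combinationCount(n, order),
                    betaCache = numeric(1), beta0 = b0, computeAlpha = FALSE)
  values <- rep(NA_real_, n^order)
  idx0 <- res[, seq_len(order), drop = FALSE] - 1
  lin <- as.vector(idx0 %*% n^(seq_len(order) - 1))
  values[lin + 1] <- res[, order + 1]
  new("BetaCache", order = order, n = as.integer(n),
      snvIds = enc$case@snvIds, values = values)
}

#' Look up a cached beta value
#'
#' @param cache a \linkS4class{BetaCache}.
#' @param tuple SNV ids or indices of length \code{cache@order} (ignored and
#'   optional for an order-0 cache).
#' @return the stored beta.
#' @export
betaLookup <- function(cache, tuple = NULL) {
  stopifnot(is(cache, "BetaCache"))
  if (cache@order == 0L) return(cache@values[1])
  idx <- sort(.resolveTuple(cache@snvIds, tuple))
  if (length(idx) != cache@order)
    stop("tuple length must equal the cache order (", cache@order, ")")
  v <- cache@values[sum((idx - 1) * cache@n^(seq_along(idx) - 1)) + 1]
  if (is.na(v)) stop("tuple not present in cache")
  v
}
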