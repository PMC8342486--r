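.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Permute a phenotype vector
#'
#' Uniformly random relabeling of the samples that preserves the case and
#' control counts (a label permutation), reproducible for a given seed.
#'
#' @param phenotype a phenotype factor (levels control/case) or 0/1 vector.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return permuted phenotype factor with levels control/case.
#' @export
permutePhenotype <- function(phenotype, seed = NULL) {
  ph <- .asPhenotypeFactor(phenotype)
  doPerm <- function() ph[sample.int(length(ph))]
  if (is.null(seed)) doPerm() else .withSeed(seed, doPerm())
}

#' Permutation null distribution of alpha or beta
#'
#' Recomputes the statistic of one SNV tuple under \code{nPerm} phenotype
#' permutations that preserve the cohort sizes.  Genotypes are fixed, so each
#' sample's contingency-table row is computed once and only the case/control
#' column assignment is redrawn per permutation; for alpha the (m-1)-subset
#' betas are recomputed under the same permutation.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param tuple SNV ids or indices (length 1..4).
#' @param statistic \code{"alpha"} or \code{"beta"}.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed (required, for reproducible published runs).
#' @return A \linkS4class{NullDistribution}.
#' @export
nullDistribution <- function(x, tuple, statistic = c("alpha", "beta"),
                             nPerm = 1000, seed) {
  stopifnot(is(x, "GenotypeExperiment"))
  statistic <- match.arg(statistic)
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  seed <- as.integer(seed)
  idx <- .resolveTuple(snvIds(x), tuple)
  m <- length(idx)
  g <- genotypes(x)[idx, , drop = FALSE]
  nSamp <- ncol(g)
  nCase <- nCases(x)
  if (nCase == 0L || nCase == nSamp) stop("both cohorts must be non-empty")

  rowsFull <- as.integer(colSums(g * 3^(seq_len(m) - 1L))) + 1L
  nbFull <- 3L^m
  subsets <- NULL
  if (statistic == "alpha" && m > 1L) {
    subsets <- lapply(seq_len(m), function(drop) {
      gs <- g[-drop, , drop = FALSE]
      list(rows = as.integer(colSums(gs * 3^(seq_len(m - 1L) - 1L))) + 1L,
           nb = 3L^(m - 1L))
    })
  }
  b0 <- purity(nCase, nSamp - nCase)

  statOne <- function(caseSel) {
    xs <- tabulate(rowsFull[caseSel], nbins = nbFull)
    ys <- tabulate(rowsFull[-caseSel], nbins = nbFull)
    b <- .betaFromCounts(xs, ys, nSamp)
    if (statistic == "beta") return(b)
    best <- if (m == 1L) b0 else max(vapply(subsets, function(s) {
      xs <- tabulate(s$rows[caseSel], nbins = s$nb)
      ys <- tabulate(s$rows[-caseSel], nbins = s$nb)
      .betaFromCounts(xs, ys, nSamp)
    }, numeric(1)))
    max(b - best, 0)
  }

  samples <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
    statOne(sample.int(nSamp, nCase)), numeric(1)))
  new("NullDistribution", statistic = statistic, snvIds = snvIds(x)[idx],
      samples = samples, nPerm = nPerm, seed = seed)
}

#' Empirical permutation p-value
#'
#' The plain one-sided ratio: the fraction of permuted-data statistics that
#' are equal to or larger than the observed value (only larger alpha/beta
#' values count as extreme).  E.g. 20 of 1000 permutations at or above the
#' observation gives p = 0.02.
#'
#' @param null a \linkS4class{NullDistribution}.
#' @param observed statistic value on the real (unpermuted) phenotype.
#' @return p in \code{{0, 1/nPerm, ..., 1}}.
#' @export
empiricalPvalue <- function(null, observed) {
  stopifnot(is(null, "NullDistribution"))
  if (null@nPerm < 1L) stop("empty null distribution")
  mean(null@samples >= observed)
}

#' Fitted-tail permutation p-value
#'
#' The empirical ratio cannot resolve p-values below 1/nPerm, so a continuous
#' distribution is fitted to the permutation null and the p-value reported as
#' 1 - CDF(observed).  The null of alpha/beta is positive and right-skewed,
#' so a Gamma is fitted by maximum likelihood after shifting the values just
#' below the null minimum (shift = min - max(1e-8, 1e-3 * range), keeping all
#' shifted values strictly positive).  If the Gamma fit fails to converge a
#' Normal is used; a degenerate (zero-variance) null falls back to the
#' empirical ratio with a warning.  The result is floored at the smallest
#' representable positive double.
#'
#' @param null a \linkS4class{NullDistribution} with at least 30 samples.
#' @param observed observed statistic value.
#' @return tail probability in (0, 1].
#' @export
fittedPvalue <- function(null, observed) {
  stopifnot(is(null, "NullDistribution"))
  s <- null@samples
  if (length(s) < 30L) stop("fitted p-value needs at least 30 permutations")
  if (stats::var(s) == 0) {
    warning("degenerate permutation null (zero variance); ",
            "falling back to the empirical ratio")
    return(empiricalPvalue(null, observed))
  }
  loc <- min(s) - max(1e-8, 1e-3 * (max(s) - min(s)))
  p <- tryCatch({
    fit <- suppressWarnings(fitdistrplus::fitdist(s - loc, "gamma"))
    1 - stats::pgamma(observed - loc, shape = fit$estimate[["shape"]],
                      rate = fit$estimate[["rate"]])
  }, error = function(e) {
    1 - stats::pnorm(observed, mean = mean(s), sd = stats::sd(s))
  })
  max(p, .Machine$double.xmin)
}

#' Bonferroni correction at a given interaction order
#'
#' Multiplies a p-value by the number of m-SNV tests among n SNVs
#' (\code{combinationCount(n, m)}) and caps at 1; e.g. 100 SNVs give 100,
#' 4950 and 161,700 tests for orders 1, 2 and 3.
#'
#' @param p p-value(s) in \code{[0, 1]}.
#' @param n number of SNVs.
#' @param m interaction order.
#' @return corrected value(s), capped at 1.
#' @export
bonferroni <- function(p, n, m) {
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  pmin(1, p * combinationCount(n, m))
}

#' Permutation p-values for a set of tuples
#'
#' Convenience wrapper running [nullDistribution()], [empiricalPvalue()],
#' [fittedPvalue()] and the per-order [bonferroni()] correction for each
#' tuple in a result table.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param tuples data.frame whose \code{SNV_1..SNV_m} columns name the
#'   tuples (e.g. a per-order element of [exhaustiveSearch()] output), or a
#'   list of id vectors.
#' @param statistic \code{"alpha"} or \code{"beta"}.
#' @param nPerm permutations per tuple.
#' @param seed integer master seed; per-tuple seeds are derived from it.
#' @return data.frame: \code{TUPLE}, \code{OBSERVED}, \code{P_EMPIRICAL},
#'   \code{P_FITTED}, \code{P_BONFERRONI}, \code{N_TESTS}.
#' @export
permutationPvalues <- function(x, tuples, statistic = c("alpha", "beta"),
                               nPerm = 1000, seed) {
  statistic <- match.arg(statistic)
  if (is.data.frame(tuples)) {
    snvCols <- grep("^SNV_", names(tuples))
    tuples <- lapply(seq_len(nrow(tuples)), function(i)
      unlist(tuples[i, snvCols], use.names = FALSE))
  }
  seed <- as.integer(seed)
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(tuples)))
  n <- nrow(x)
  rows <- lapply(seq_along(tuples), function(i) {
    tup <- tuples[[i]]
    m <- length(tup)
    obs <- .observedStatistic(x, tup, statistic)
    nd <- nullDistribution(x, tup, statistic, nPerm = nPerm, seed = seeds[i])
    pf <- fittedPvalue(nd, obs)
    data.frame(TUPLE = paste(sort(snvIds(x)[.resolveTuple(snvIds(x), tup)],
                                  method = "radix"), collapse = ","),
               OBSERVED = obs,
               P_EMPIRICAL = empiricalPvalue(nd, obs),
               P_FITTED = pf,
               P_BONFERRONI = bonferroni(pf, n, m),
               N_TESTS = combinationCount(n, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.observedStatistic <- function(x, tuple, statistic) {
  idx <- .resolveTuple(snvIds(x), tuple)
  m <- length(idx)
  b <- betaFromTable(countNaive(x, idx))
  if (statistic == "beta") return(b)
  best <- if (m == 1L) betaZero(x) else
    max(vapply(seq_len(m), function(drop)
      betaFromTable(countNaive(x, idx[-drop])), numeric(1)))
  alphaFromBetas(b, rep(best, m), m)
}
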