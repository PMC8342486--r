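#' Size of the exhaustive search space
#'
#' Exact number of m-SNV tuples among n SNVs, \eqn{\binom{n}{m}}; e.g. 1000
#' SNVs give 499,500 pairs, 166,167,000 triplets and 41,417,124,750
#' quadruplets, and 100 SNVs give the 100 / 4950 / 161,700 test counts used
#' for per-order Bonferroni correction.
#'
#' @param n number of SNVs.
#' @param m interaction order, 0 < m <= n.
#' @return exact count (numeric; exact up to 2^53).
#' @export
combinationCount <- function(n, m) {
  if (any(m <= 0) || any(m > n)) stop("order m must satisfy 0 < m <= n")
  choose(n, m)
}

#' Balanced partition of the combination space
#'
#' Splits the colex-ordered combination indices \code{[0, C(n, m))} into
#' \code{workers} contiguous ranges whose sizes differ by at most one.  Every
#' range is identified by its global start index and size; [colexUnrank()]
#' maps a start index back to its tuple, so partitions can be processed
#' independently and merged deterministically.
#'
#' @param n number of SNVs.
#' @param m interaction order.
#' @param workers number of partitions (>= 1).
#' @return data.frame with columns \code{start} (0-based) and \code{size};
#'   empty trailing ranges are kept so exactly \code{workers} rows return.
#' @export
partitionCombinations <- function(n, m, workers) {
  workers <- as.integer(workers)
  if (workers < 1L) stop("workers must be >= 1")
  C <- combinationCount(n, m)
  base <- C %/% workers
  extra <- C %% workers
  size <- rep(base, workers) + (seq_len(workers) <= extra)
  data.frame(start = cumsum(c(0, size[-workers])), size = size)
}

#' Unrank a combination in colexicographic order
#'
#' The combinatorial number system: rank r corresponds to the unique
#' 0-based increasing tuple \eqn{a_1 < \dots < a_m} with
#' \eqn{r = \sum_i \binom{a_i}{i}}.  This is the fixed bijection used to
#' assign combination ranges to workers.
#'
#' @param r 0-based rank, \code{0 <= r < C(n, m)}.
#' @param m tuple length.
#' @return 0-based increasing integer vector of length m.
#' @export
colexUnrank <- function(r, m) {
  m <- as.integer(m)
  a <- integer(m)
  for (i in m:1) {
    c <- i - 1L
    while (choose(c + 1L, i) <= r) c <- c + 1L
    a[i] <- c
    r <- r - choose(c, i)
  }
  a
}

.canonicalResult <- function(res, ids, m, computeAlpha) {
  # sort ids within tuple (C-locale radix), then order by metric desc with
  # lexicographic id tie-break for fully deterministic output
  tupleIds <- matrix(ids[res[, seq_len(m), drop = FALSE]], ncol = m)
  if (m > 1L)
    tupleIds <- t(apply(tupleIds, 1L, sort, method = "radix"))
  df <- data.frame(tupleIds, BETA = res[, m + 1],
                   ALPHA = res[, m + 2], stringsAsFactors = FALSE)
  names(df)[seq_len(m)] <- paste0("SNV_", seq_len(m))
  df
}

.orderResult <- function(df, m, metric) {
  key <- df[[toupper(metric)]]
  ord <- do.call(order, c(list(-key),
                          lapply(seq_len(m), function(j)
                            df[[paste0("SNV_", j)]]),
                          list(method = "radix")))
  df[ord, , drop = FALSE]
}

#' Exhaustive m-SNV interaction search
#'
#' Tests every m-SNV tuple for each requested order, computing beta (combined
#' association power) and, when \code{metric = "alpha"}, the interaction
#' effect size against the precomputed (m-1)-order beta cache.  Results are
#' ranked by the chosen metric (descending), ties broken by the
#' lexicographic tuple of SNV ids; tuples are reported with their ids in
#' sorted order (alpha and beta are invariant to slot order).  The
#' combination space is processed in \code{workers} balanced colex ranges;
#' the merged, sorted output is identical for any worker count.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param orders subset of 1:4.
#' @param metric \code{"alpha"} or \code{"beta"}; ranking metric.
#' @param topK optional: keep only the top K tuples per order.
#' @param threshold optional: keep only tuples with metric >= threshold.
#' @param workers number of deterministic partitions (sequentially
#'   processed).
#' @return Named list (one element per order, names \code{"1"}..) of
#'   data.frames with columns \code{SNV_1..SNV_m}, \code{BETA},
#'   \code{ALPHA}.
#' @examples
#' res <- exhaustiveSearch(demoPairDataset(), orders = 2)
#' res[["2"]]
#' @export
exhaustiveSearch <- function(x, orders = 2, metric = c("alpha", "beta"),
                             topK = NULL, threshold = NULL, workers = 1) {
  stopifnot(is(x, "GenotypeExperiment"))
  metric <- match.arg(metric)
  orders <- sort(unique(as.integer(orders)))
  if (length(orders) == 0L || any(orders < 1L) || any(orders > 4L))
    stop("orders must be a non-empty subset of 1:4")
  n <- nrow(x)
  if (n < max(orders)) stop("fewer SNVs than the requested order")
  enc <- encodeCohorts(x)
  ids <- snvIds(x)
  b0 <- purity(nCases(x), nControls(x))

  out <- list()
  for (m in orders) {
    computeAlpha <- TRUE  # alpha is cheap once the cache exists; always emit
    cache <- buildBetaCache(enc, m - 1L)
    parts <- partitionCombinations(n, m, workers)
    chunks <- lapply(seq_len(nrow(parts)), function(i) {
      if (parts$size[i] == 0) return(NULL)
      cpp_search(enc$case@shifts, enc$control@shifts, n,
                 startCombo = colexUnrank(parts$start[i], m),
                 count = parts$size[i],
                 betaCache = if (m == 1L) numeric(1) else cache@values,
                 beta0 = b0, computeAlpha = computeAlpha)
    })
    res <- do.call(rbind, chunks)
    df <- .orderResult(.canonicalResult(res, ids, m, computeAlpha), m, metric)
    if (!is.null(threshold)) df <- df[df[[toupper(metric)]] >= threshold, ,
                                      drop = FALSE]
    if (!is.null(topK)) df <- head(df, topK)
    rownames(df) <- NULL
    out[[as.character(m)]] <- df
  }
  out
}

#' Best interaction per SNV
#'
#' For every SNV, reports the m-SNV tuple containing it with the highest
#' interaction effect size (alpha), for each requested order; ties are broken
#' by the lexicographic partner tuple.
#'
#' @param x a \linkS4class{GenotypeExperiment}.
#' @param orders subset of 2:4.
#' @param workers passed to [exhaustiveSearch()].
#' @return data.frame with columns \code{SNV}, \code{ORDER}, \code{PARTNERS}
#'   (comma-separated co-members), \code{ALPHA}.
#' @export
bestMode <- function(x, orders = 2:4, workers = 1) {
  orders <- sort(unique(as.integer(orders)))
  if (any(orders < 2L) || any(orders > 4L))
    stop("best mode is defined for orders 2..4")
  res <- exhaustiveSearch(x, orders = orders, metric = "alpha",
                          workers = workers)
  ids <- snvIds(x)
  out <- list()
  for (m in orders) {
    df <- res[[as.character(m)]]  # already alpha-desc, id tie-broken
    tupleIds <- as.matrix(df[, seq_len(m), drop = FALSE])
    for (snv in ids) {
      hit <- which(rowSums(tupleIds == snv) > 0)[1]
      partners <- setdiff(tupleIds[hit, ], snv)
      out[[length(out) + 1L]] <- data.frame(
        SNV = snv, ORDER = m,
        PARTNERS = paste(partners, collapse = ","),
        ALPHA = df$ALPHA[hit], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write per-order search results as TSV
#'
#' @param results the list returned by [exhaustiveSearch()].
#' @param dir output directory (created if absent); one file
#'   \code{order<m>.tsv} per order.
#' @return invisibly, the written paths.
#' @export
writeSearchResults <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in names(results)) {
    p <- file.path(dir, paste0("order", m, ".tsv"))
    write.table(results[[m]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
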