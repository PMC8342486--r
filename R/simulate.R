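#' Construct a penetrance model
#'
#' @param mafs minor-allele frequencies of the m interacting SNVs, in
#'   (0, 0.5].
#' @param penetrance disease probability per genotype combination: numeric
#'   vector of length 3^m indexed like \linkS4class{ContingencyTable} rows
#'   (first SNV fastest-varying).
#' @param label model name.
#' @return A \linkS4class{PenetranceModel}.
#' @export
penetranceModel <- function(mafs, penetrance, label = "model") {
  new("PenetranceModel", m = length(mafs), mafs = as.numeric(mafs),
      penetrance = as.numeric(penetrance), label = label)
}

#' Built-in penetrance model library
#'
#' Documented epistasis models used throughout the test-bench:
#' \describe{
#'   \item{\code{xorPairModel}}{strict-and-pure 2-SNV parity (XOR) model:
#'     penetrance \code{penHigh} where the genotype codes have odd sum,
#'     \code{penLow} elsewhere.  At MAF 0.5 each SNV's marginal penetrance is
#'     flat, so the association is visible only in the pair.}
#'   \item{\code{parityTripletModel}}{3-SNV analogue on the parity of the
#'     summed codes.}
#'   \item{\code{thresholdModel}}{penetrance \code{penHigh} when the summed
#'     codes reach \code{threshold}; carries marginal effects.}
#'   \item{\code{marginalModel}}{single-SNV additive model with penetrance
#'     \code{0.5 + effect * (g - 1)}.}
#'   \item{\code{flatModel}}{null model: constant penetrance, no association.}
#' }
#' @param maf minor-allele frequency (recycled across the interacting SNVs).
#' @param penHigh,penLow penetrance at the high/low genotype classes.
#' @param effect marginal effect size in (0, 0.5].
#' @param threshold minimum summed genotype code for \code{penHigh}.
#' @param m model order (flatModel only).
#' @param prob constant penetrance (flatModel only).
#' @return A \linkS4class{PenetranceModel}.
#' @name modelLibrary
NULL

#' @rdname modelLibrary
#' @export
xorPairModel <- function(maf = 0.5, penHigh = 1, penLow = 0) {
  g <- expand.grid(0:2, 0:2)
  pen <- ifelse((g[, 1] + g[, 2]) %% 2 == 1, penHigh, penLow)
  penetranceModel(c(maf, maf), pen, "xor-pair")
}

#' @rdname modelLibrary
#' @export
parityTripletModel <- function(maf = 0.5, penHigh = 1, penLow = 0) {
  g <- expand.grid(0:2, 0:2, 0:2)
  pen <- ifelse((g[, 1] + g[, 2] + g[, 3]) %% 2 == 1, penHigh, penLow)
  penetranceModel(c(maf, maf, maf), pen, "parity-triplet")
}

#' @rdname modelLibrary
#' @export
thresholdModel <- function(maf = 0.3, threshold = 3, penHigh = 0.9,
                           penLow = 0.1) {
  g <- expand.grid(0:2, 0:2)
  pen <- ifelse(g[, 1] + g[, 2] >= threshold, penHigh, penLow)
  penetranceModel(c(maf, maf), pen, "threshold-pair")
}

#' @rdname modelLibrary
#' @export
marginalModel <- function(maf = 0.25, effect = 0.2) {
  penetranceModel(maf, 0.5 + effect * (0:2 - 1), "marginal")
}

#' @rdname modelLibrary
#' @export
flatModel <- function(m = 2, maf = 0.3, prob = 0.5) {
  penetranceModel(rep(maf, m), rep(prob, 3^m), "flat-null")
}

#' Read / write a penetrance model as JSON
#'
#' Small interchange format: an object with fields \code{label}, \code{mafs}
#' and \code{penetrance} (flat 3^m vector, first SNV fastest-varying).
#'
#' @param path JSON file path.
#' @return [readPenetranceModel()] returns a \linkS4class{PenetranceModel}.
#' @export
readPenetranceModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  penetranceModel(obj$mafs, obj$penetrance,
                  if (is.null(obj$label)) "model" else obj$label)
}

#' @rdname readPenetranceModel
#' @param model a \linkS4class{PenetranceModel}.
#' @export
writePenetranceModel <- function(model, path) {
  jsonlite::write_json(list(label = model@label, mafs = model@mafs,
                            penetrance = model@penetrance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.drawGenotypes <- function(n, mafs) {
  # HWE: genotype code ~ Binomial(2, maf)
  vapply(mafs, function(f) stats::rbinom(n, 2L, f), integer(n))
}

#' Simulate a case/control dataset with a planted interaction
#'
#' Draws truth-SNV genotypes under Hardy-Weinberg equilibrium from the
#' model's MAFs, assigns disease status Bernoulli(penetrance of the genotype
#' combination), and rejection-samples batches until exactly \code{nCases}
#' cases and \code{nControls} controls are collected.  Noise SNVs are drawn
#' independently of the phenotype with MAFs uniform in \code{noiseMafRange}.
#' Truth SNVs are placed at seeded random column positions.
#'
#' @param model a \linkS4class{PenetranceModel}.
#' @param nCases,nControls target cohort sizes.
#' @param nSnvs total SNV count (>= model order).
#' @param noiseMafRange MAF interval for noise SNVs.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param maxRounds rejection-sampling cap: at most \code{maxRounds} batches
#'   of \code{2 * (nCases + nControls)} draws before giving up.
#' @return A \linkS4class{SimulatedDataset}; \code{truthTuples()} holds the
#'   planted column indices.
#' @export
simulateDataset <- function(model, nCases = 1000, nControls = 1000,
                            nSnvs = 100, noiseMafRange = c(0.05, 0.5),
                            seed, maxRounds = 100) {
  stopifnot(is(model, "PenetranceModel"))
  m <- model@m
  if (nSnvs < m) stop("nSnvs must be at least the model order")
  seed <- as.integer(seed)
  .withSeed(seed, {
    batch <- 2L * (nCases + nControls)
    caseG <- matrix(0L, 0L, m); ctrlG <- matrix(0L, 0L, m)
    for (round in seq_len(maxRounds)) {
      g <- .drawGenotypes(batch, model@mafs)
      row <- as.integer(g %*% 3^(seq_len(m) - 1L)) + 1L
      y <- stats::rbinom(batch, 1L, model@penetrance[row])
      if (nrow(caseG) < nCases)
        caseG <- rbind(caseG, g[y == 1L, , drop = FALSE])
      if (nrow(ctrlG) < nControls)
        ctrlG <- rbind(ctrlG, g[y == 0L, , drop = FALSE])
      if (nrow(caseG) >= nCases && nrow(ctrlG) >= nControls) break
    }
    if (nrow(caseG) < nCases || nrow(ctrlG) < nControls)
      stop("could not attain the requested cohort sizes under this ",
           "penetrance model within ", maxRounds, " rejection rounds")
    truthG <- rbind(caseG[seq_len(nCases), , drop = FALSE],
                    ctrlG[seq_len(nControls), , drop = FALSE])
    nSamp <- nCases + nControls
    phen <- rep(c(1, 0), c(nCases, nControls))

    g <- matrix(0L, nSamp, nSnvs)
    truthPos <- sort(sample.int(nSnvs, m))
    noisePos <- setdiff(seq_len(nSnvs), truthPos)
    if (length(noisePos)) {
      noiseMafs <- stats::runif(length(noisePos), noiseMafRange[1],
                                noiseMafRange[2])
      g[, noisePos] <- .drawGenotypes(nSamp, noiseMafs)
    }
    g[, truthPos] <- truthG
    dimnames(g) <- list(paste0("S", seq_len(nSamp)),
                        paste0("SNV_", seq_len(nSnvs)))
    ge <- GenotypeExperiment(g, phenotype = phen)
    new("SimulatedDataset", data = ge, truth = list(truthPos), seed = seed)
  })
}

#' Detection power of the search over replicate simulations
#'
#' For each model, simulates \code{nDatasets} replicate datasets, runs the
#' exhaustive alpha search at the model's order, and counts how often the
#' planted truth tuple is ranked first; any tuple ranked above the truth is a
#' false positive.
#'
#' @param models list of \linkS4class{PenetranceModel} objects (or a single
#'   model).
#' @param nDatasets replicates per model.
#' @param nCases,nControls,nSnvs,noiseMafRange passed to
#'   [simulateDataset()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return data.frame with columns \code{label}, \code{power},
#'   \code{nDatasets}.
#' @export
detectionPower <- function(models, nDatasets = 100, nCases = 1000,
                           nControls = 1000, nSnvs = 100,
                           noiseMafRange = c(0.05, 0.5), seed) {
  if (is(models, "PenetranceModel")) models <- list(models)
  seed <- as.integer(seed)
  seeds <- .withSeed(seed,
                     sample.int(.Machine$integer.max - 1L,
                                length(models) * nDatasets))
  dim(seeds) <- c(length(models), nDatasets)
  rows <- lapply(seq_along(models), function(k) {
    model <- models[[k]]
    hits <- vapply(seq_len(nDatasets), function(i) {
      sim <- simulateDataset(model, nCases, nControls, nSnvs, noiseMafRange,
                             seed = seeds[k, i])
      top <- exhaustiveSearch(simData(sim), orders = model@m,
                              metric = "alpha", topK = 1)[[as.character(model@m)]]
      topIds <- sort(unlist(top[1, seq_len(model@m)], use.names = FALSE),
                     method = "radix")
      truthIds <- sort(snvIds(simData(sim))[truthTuples(sim)[[1]]],
                       method = "radix")
      identical(topIds, truthIds)
    }, logical(1))
    data.frame(label = model@label, power = mean(hits),
               nDatasets = nDatasets, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deterministic two-SNV demonstration cohort
#'
#' A fixed dataset of two SNVs, A and B, built so that the 2-SNV contingency
#' table has exactly 34 cases and 46 controls in the double-heterozygote
#' (0/1, 0/1) cell while every other genotype-combination cell holds 10 cases
#' and 10 controls (so the case column sums to 114 and the control column to
#' 126).  No randomness is involved; useful as a known-answer input for the
#' counting engines.
#'
#' @return A \linkS4class{GenotypeExperiment} with 240 samples.
#' @examples
#' counts(countOneVector(encodeCohorts(demoPairDataset())$case,
#'                       encodeCohorts(demoPairDataset())$control,
#'                       c("A", "B")))["0/1,0/1", ]
#' @export
demoPairDataset <- function() {
  cells <- expand.grid(A = 0:2, B = 0:2)
  nCase <- ifelse(cells$A == 1 & cells$B == 1, 34L, 10L)
  nCtrl <- ifelse(cells$A == 1 & cells$B == 1, 46L, 10L)
  g <- rbind(cells[rep(seq_len(9), nCase), ], cells[rep(seq_len(9), nCtrl), ])
  phen <- rep(c(1, 0), c(sum(nCase), sum(nCtrl)))
  g <- as.matrix(g)
  rownames(g) <- paste0("S", seq_len(nrow(g)))
  GenotypeExperiment(g, phenotype = phen)
}

#' Simulate a dataset with marginal, pairwise and triplet truth effects
#'
#' Generates a dataset whose phenotype mixes three independent truth
#' components: a marginal effect at one SNV (A), a pure pairwise parity
#' effect at two SNVs (B, C) and a pure triplet parity effect at three SNVs
#' (D, E, F).  All truth SNVs have MAF 0.5, so at the stated effect sizes the
#' pair and triplet components carry no marginal or lower-order signal; the
#' per-sample penetrance is
#' \code{0.5 + marginal*(gA-1)/2 + pair*parity(B,C)/2 + triplet*parity(D,E,F)/2}
#' clipped to [0, 1], with parity = +1 (odd summed codes) or -1.
#'
#' @param nSnvs total SNV count (>= 6).
#' @param nCases,nControls cohort sizes.
#' @param effects named numeric: \code{marginal}, \code{pair},
#'   \code{triplet} amplitudes in [0, 0.5].
#' @param noiseMafRange MAF interval for noise SNVs.
#' @param seed integer seed.
#' @param maxRounds rejection-sampling cap, as in [simulateDataset()].
#' @return A \linkS4class{SimulatedDataset} whose \code{truthTuples()} lists
#'   the marginal SNV, the pair and the triplet (in that order).
#' @export
simulateMixedOrderDataset <- function(nSnvs = 100, nCases = 1000,
                                      nControls = 1000,
                                      effects = c(marginal = 0.2,
                                                  pair = 0.25,
                                                  triplet = 0.25),
                                      noiseMafRange = c(0.05, 0.5), seed,
                                      maxRounds = 100) {
  if (nSnvs < 6L) stop("need at least 6 SNVs for the three truth components")
  stopifnot(all(c("marginal", "pair", "triplet") %in% names(effects)))
  seed <- as.integer(seed)
  .withSeed(seed, {
    batch <- 2L * (nCases + nControls)
    caseG <- matrix(0L, 0L, 6L); ctrlG <- matrix(0L, 0L, 6L)
    pen <- function(g) {
      parity <- function(s) ifelse(s %% 2 == 1, 1, -1)
      p <- 0.5 + effects[["marginal"]] * (g[, 1] - 1) / 2 +
        effects[["pair"]] * parity(g[, 2] + g[, 3]) / 2 +
        effects[["triplet"]] * parity(g[, 4] + g[, 5] + g[, 6]) / 2
      pmin(pmax(p, 0), 1)
    }
    for (round in seq_len(maxRounds)) {
      g <- .drawGenotypes(batch, rep(0.5, 6))
      y <- stats::rbinom(batch, 1L, pen(g))
      if (nrow(caseG) < nCases)
        caseG <- rbind(caseG, g[y == 1L, , drop = FALSE])
      if (nrow(ctrlG) < nControls)
        ctrlG <- rbind(ctrlG, g[y == 0L, , drop = FALSE])
      if (nrow(caseG) >= nCases && nrow(ctrlG) >= nControls) break
    }
    if (nrow(caseG) < nCases || nrow(ctrlG) < nControls)
      stop("could not attain the requested cohort sizes")
    truthG <- rbind(caseG[seq_len(nCases), , drop = FALSE],
                    ctrlG[seq_len(nControls), , drop = FALSE])
    nSamp <- nCases + nControls
    g <- matrix(0L, nSamp, nSnvs)
    truthPos <- sort(sample.int(nSnvs, 6L))
    noisePos <- setdiff(seq_len(nSnvs), truthPos)
    if (length(noisePos))
      g[, noisePos] <- .drawGenotypes(
        nSamp, stats::runif(length(noisePos), noiseMafRange[1],
                            noiseMafRange[2]))
    g[, truthPos] <- truthG
    dimnames(g) <- list(paste0("S", seq_len(nSamp)),
                        paste0("SNV_", seq_len(nSnvs)))
    ge <- GenotypeExperiment(g, phenotype = rep(c(1, 0), c(nCases, nControls)))
    new("SimulatedDataset", data = ge,
        truth = list(truthPos[1], truthPos[2:3], truthPos[4:6]),
        seed = seed)
  })
}
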