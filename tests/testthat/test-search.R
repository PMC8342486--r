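test_that("combination counts are exact", {
  expect_equal(combinationCount(1000, 2), 499500)
  expect_equal(combinationCount(1000, 3), 166167000)
  expect_equal(combinationCount(100, 3), 161700)
  expect_error(combinationCount(3, 4), "0 < m <= n")
})

test_that("colex unranking is a bijection onto sorted tuples", {
  C <- combinationCount(6, 3)
  tuples <- vapply(0:(C - 1), function(r) colexUnrank(r, 3), integer(3))
  expect_true(all(apply(tuples, 2, function(a) all(diff(a) > 0))))
  expect_equal(nrow(unique(t(tuples))), C)
  expect_equal(colexUnrank(0, 3), 0:2)
})

test_that("partitioning balances the combination space", {
  p <- partitionCombinations(5, 2, 3)          # C = 10 -> sizes 4, 3, 3
  expect_equal(p$size, c(4, 3, 3))
  expect_equal(p$start, c(0, 4, 7))
  p1 <- partitionCombinations(5, 2, 1)
  expect_equal(p1$size, 10)
  expect_equal(p1$start, 0)
})

test_that("exhaustive search is complete and matches per-SNV oracles", {
  ge <- randomGenotypeExperiment(8, 50, 45, seed = 2)
  res <- exhaustiveSearch(ge, orders = 1:3, metric = "beta")
  expect_equal(nrow(res[["1"]]), 8)
  expect_equal(nrow(res[["2"]]), combinationCount(8, 2))
  expect_equal(nrow(res[["3"]]), combinationCount(8, 3))
  # order-1 betas match direct computation per SNV
  for (i in seq_len(8)) {
    id <- snvIds(ge)[i]
    expect_equal(res[["1"]]$BETA[res[["1"]]$SNV_1 == id],
                 betaFromTable(countNaive(ge, i)))
  }
  # output sorted by the metric, descending
  expect_true(all(diff(res[["2"]]$BETA) <= 0))
})

test_that("topK and threshold limit the ranked output", {
  ge <- randomGenotypeExperiment(10, 40, 40, seed = 3)
  res <- exhaustiveSearch(ge, orders = 2, metric = "alpha", topK = 3)[["2"]]
  expect_equal(nrow(res), 3)
  expect_true(all(diff(res$ALPHA) <= 0))
  thr <- exhaustiveSearch(ge, orders = 2, metric = "alpha",
                          threshold = res$ALPHA[2])[["2"]]
  expect_true(all(thr$ALPHA >= res$ALPHA[2]))
  expect_gte(nrow(thr), 2)
})

test_that("a strong planted pair is ranked first by alpha", {
  sim <- simulateDataset(xorPairModel(), nCases = 500, nControls = 500,
                         nSnvs = 30, seed = 17)
  top <- exhaustiveSearch(simData(sim), orders = 2, metric = "alpha",
                          topK = 1)[["2"]]
  truth <- sort(snvIds(simData(sim))[truthTuples(sim)[[1]]], method = "radix")
  expect_equal(sort(unlist(top[1, 1:2], use.names = FALSE)), truth)
  expect_gt(top$ALPHA[1], 0.4)
})

test_that("results are identical for any worker count", {
  ge <- randomGenotypeExperiment(12, 30, 30, seed = 4)
  r1 <- exhaustiveSearch(ge, orders = 2:3, workers = 1)
  r2 <- exhaustiveSearch(ge, orders = 2:3, workers = 2)
  r8 <- exhaustiveSearch(ge, orders = 2:3, workers = 8)
  expect_identical(r1, r2)
  expect_identical(r1, r8)
})

test_that("results are stable under SNV column reordering", {
  ge <- randomGenotypeExperiment(7, 40, 40, seed = 5)
  perm <- sample(7)
  gePerm <- GenotypeExperiment(t(genotypes(ge))[, perm],
                               phenotype = phenotype(ge))
  a <- exhaustiveSearch(ge, orders = 2)[["2"]]
  b <- exhaustiveSearch(gePerm, orders = 2)[["2"]]
  key <- function(df) paste(df$SNV_1, df$SNV_2)
  expect_setequal(key(a), key(b))
  b <- b[match(key(a), key(b)), ]
  expect_equal(a$BETA, b$BETA)
  expect_equal(a$ALPHA, b$ALPHA)
})

test_that("best mode reports each SNV's argmax tuple", {
  ge <- randomGenotypeExperiment(5, 60, 55, seed = 6)
  best <- bestMode(ge, orders = 2)
  expect_equal(nrow(best), 5)
  res <- exhaustiveSearch(ge, orders = 2, metric = "alpha")[["2"]]
  for (i in seq_len(5)) {
    id <- snvIds(ge)[i]
    mine <- res[res$SNV_1 == id | res$SNV_2 == id, ]
    expect_equal(best$ALPHA[best$SNV == id], max(mine$ALPHA))
  }
  # a dominating pair is reported by both of its members
  sim <- simulateDataset(xorPairModel(), nCases = 300, nControls = 300,
                         nSnvs = 6, seed = 23)
  tru <- snvIds(simData(sim))[truthTuples(sim)[[1]]]
  b2 <- bestMode(simData(sim), orders = 2)
  expect_equal(b2$PARTNERS[b2$SNV == tru[1]], tru[2])
  expect_equal(b2$PARTNERS[b2$SNV == tru[2]], tru[1])
})

test_that("constant SNVs yield zero interaction gain with each other", {
  g <- cbind(A = rep(0L, 40), B = rep(2L, 40), C = rbinom(40, 2, 0.4))
  rownames(g) <- paste0("S", 1:40)
  ge <- GenotypeExperiment(g, phenotype = rep(c(1, 0), 20))
  res <- exhaustiveSearch(ge, orders = 2)[["2"]]
  ab <- res[res$SNV_1 == "A" & res$SNV_2 == "B", ]
  expect_equal(ab$ALPHA, 0)
})

test_that("search results write one TSV per order", {
  ge <- randomGenotypeExperiment(5, 20, 20, seed = 9)
  res <- exhaustiveSearch(ge, orders = 1:2)
  d <- withr::local_tempdir()
  writeSearchResults(res, d)
  f2 <- read.delim(file.path(d, "order2.tsv"))
  expect_equal(names(f2), c("SNV_1", "SNV_2", "BETA", "ALPHA"))
  expect_equal(nrow(f2), combinationCount(5, 2))
})
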