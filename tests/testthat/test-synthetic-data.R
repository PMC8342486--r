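test_that("penetrance models validate their tables", {
  expect_error(penetranceModel(c(0.5, 0.5), rep(0.5, 8)), "3\\^m")
  expect_error(penetranceModel(0.6, rep(0.5, 3)), "\\(0, 0.5\\]")
  expect_error(penetranceModel(0.5, c(0.5, 1.2, 0)), "\\[0, 1\\]")
  m <- xorPairModel()
  expect_equal(m@m, 2L)
  expect_equal(m@penetrance[5], 0)   # (0/1, 0/1) has even code sum
  expect_equal(m@penetrance[2], 1)   # (0/1, 0/0) has odd code sum
})

test_that("penetrance models round-trip through JSON", {
  m <- thresholdModel(maf = 0.2)
  p <- withr::local_tempfile(fileext = ".json")
  writePenetranceModel(m, p)
  m2 <- readPenetranceModel(p)
  expect_equal(m2@mafs, m@mafs)
  expect_equal(m2@penetrance, m@penetrance)
  expect_equal(m2@label, m@label)
})

test_that("simulation is a pure function of parameters and seed", {
  s1 <- simulateDataset(xorPairModel(), 50, 50, nSnvs = 12, seed = 101)
  s2 <- simulateDataset(xorPairModel(), 50, 50, nSnvs = 12, seed = 101)
  expect_identical(genotypes(simData(s1)), genotypes(simData(s2)))
  expect_identical(truthTuples(s1), truthTuples(s2))
  s3 <- simulateDataset(xorPairModel(), 50, 50, nSnvs = 12, seed = 102)
  expect_false(identical(genotypes(simData(s1)), genotypes(simData(s3))))
})

test_that("simulated cohorts honour requested sizes and truth placement", {
  sim <- simulateDataset(thresholdModel(), nCases = 120, nControls = 80,
                         nSnvs = 15, seed = 55)
  ge <- simData(sim)
  expect_equal(nCases(ge), 120L)
  expect_equal(nControls(ge), 80L)
  expect_equal(nrow(ge), 15L)
  expect_true(all(truthTuples(sim)[[1]] %in% seq_len(15)))
  expect_error(simulateDataset(flatModel(prob = 0), 10, 10, nSnvs = 5,
                               seed = 1, maxRounds = 3),
               "could not attain")
})

test_that("noise SNVs follow Hardy-Weinberg genotype frequencies", {
  sim <- simulateDataset(flatModel(), nCases = 2000, nControls = 2000,
                         nSnvs = 3, seed = 77, noiseMafRange = c(0.3, 0.3))
  noise <- setdiff(1:3, truthTuples(sim)[[1]])[1]
  g <- genotypes(simData(sim))[noise, ]
  freq <- tabulate(g + 1L, 3) / length(g)
  f <- 0.3
  expect_equal(freq, c((1 - f)^2, 2 * f * (1 - f), f^2), tolerance = 0.05)
})

test_that("under a flat penetrance the planted tuple is indistinguishable", {
  # fix every SNV at the same MAF so pair alphas are exchangeable: the
  # planted tuple's rank should then be uniform over the C(12, 2) pairs
  ranks <- vapply(1:10, function(i) {
    sim <- simulateDataset(flatModel(maf = 0.4), 150, 150, nSnvs = 12,
                           seed = 1000 + i, noiseMafRange = c(0.4, 0.4))
    res <- exhaustiveSearch(simData(sim), orders = 2, metric = "alpha")[["2"]]
    truth <- sort(snvIds(simData(sim))[truthTuples(sim)[[1]]],
                  method = "radix")
    which(res$SNV_1 == truth[1] & res$SNV_2 == truth[2]) / nrow(res)
  }, numeric(1))
  expect_gt(mean(ranks), 0.2)
  expect_lt(mean(ranks), 0.8)
})

test_that("detection power reflects signal strength", {
  pow <- detectionPower(xorPairModel(), nDatasets = 5, nCases = 400,
                        nControls = 400, nSnvs = 20, seed = 12)
  expect_equal(pow$power, 1.0)   # deterministic fully penetrant model
  expect_equal(pow$nDatasets, 5)
})

test_that("detection power is monotone in sample size for a moderate model", {
  model <- xorPairModel(penHigh = 0.65, penLow = 0.35)
  sizes <- c(200, 1000, 2000)
  pow <- vapply(seq_along(sizes), function(i)
    detectionPower(model, nDatasets = 12, nCases = sizes[i] / 2,
                   nControls = sizes[i] / 2, nSnvs = 20,
                   seed = 300 + i)$power, numeric(1))
  # non-decreasing trend up to Monte-Carlo slack at 12 replicates
  expect_lte(pow[1], pow[2] + 0.2)
  expect_lte(pow[2], pow[3] + 0.2)
  expect_gte(pow[3], pow[1])
})

test_that("the demonstration cohort pins the double-heterozygote cell", {
  ge <- demoPairDataset()
  enc <- encodeCohorts(ge)
  ct <- countOneVector(enc$case, enc$control, c("A", "B"))
  expect_equal(unname(counts(ct)["0/1,0/1", ]), c(34L, 46L))
  expect_equal(sum(counts(ct)[, "case"]), 114L)       # 34 + 8 * 10
  expect_equal(sum(counts(ct)[, "control"]), 126L)    # 46 + 8 * 10
  expect_identical(counts(ct), counts(countNaive(ge, c("A", "B"))))
  # deterministic construction
  expect_identical(genotypes(ge), genotypes(demoPairDataset()))
  # survives a table write/read round trip
  p <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(ge, p)
  ge2 <- suppressMessages(readGenotypeTable(p))
  expect_identical(genotypes(ge2), genotypes(ge))
  expect_identical(phenotype(ge2), phenotype(ge))
})

test_that("mixed-order truths each win their own order", {
  sim <- simulateMixedOrderDataset(nSnvs = 30, nCases = 1000,
                                   nControls = 1000, seed = 59)
  ge <- simData(sim)
  ids <- snvIds(ge)
  res <- exhaustiveSearch(ge, orders = 1:3, metric = "alpha", topK = 1)
  truth <- truthTuples(sim)
  expect_equal(res[["1"]]$SNV_1[1], ids[truth[[1]]])
  expect_equal(sort(unlist(res[["2"]][1, 1:2], use.names = FALSE)),
               sort(ids[truth[[2]]], method = "radix"))
  expect_equal(sort(unlist(res[["3"]][1, 1:3], use.names = FALSE)),
               sort(ids[truth[[3]]], method = "radix"))
  # seeded determinism
  sim2 <- simulateMixedOrderDataset(nSnvs = 30, nCases = 1000,
                                    nControls = 1000, seed = 59)
  expect_identical(genotypes(simData(sim2)), genotypes(ge))
})
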