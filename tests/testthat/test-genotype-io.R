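test_that("genotype table round-trips and parses the documented layout", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tphenotype\tA\tB",
               "S1\t1\t0\t2",
               "S2\t1\t1\t1",
               "S3\t0\t2\t0",
               "S4\t0\t0\t1"), p)
  ge <- suppressMessages(readGenotypeTable(p))
  expect_s4_class(ge, "GenotypeExperiment")
  expect_equal(dim(genotypes(ge)), c(2L, 4L))
  expect_equal(nCases(ge), 2L)
  expect_equal(nControls(ge), 2L)
  expect_equal(unname(genotypes(ge)["A", ]), c(0L, 1L, 2L, 0L))

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(ge, p2)
  ge2 <- suppressMessages(readGenotypeTable(p2))
  expect_identical(genotypes(ge2), genotypes(ge))
  expect_identical(phenotype(ge2), phenotype(ge))
})

test_that("table reader rejects bad genotype codes and headers", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tphenotype\tA\tB",
               "S1\t1\t0\t3",
               "S2\t0\t1\t1"), p)
  expect_error(readGenotypeTable(p), "invalid genotype code")
  expect_error(readGenotypeTable(p), "S1")
  expect_error(readGenotypeTable(p), "B")

  writeLines(c("sample_id\tphenotype\tA\t",
               "S1\t1\t0\t1"), p)
  expect_error(readGenotypeTable(p), "unnamed SNV column")

  writeLines(c("sample_id\tphenotype\tA\tA",
               "S1\t1\t0\t1"), p)
  expect_error(readGenotypeTable(p), "duplicate SNV")
})

test_that("missing genotypes error by default and can drop samples", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tphenotype\tA\tB",
               "S1\t1\t0\t2",
               "S2\t1\t\t1",
               "S3\t0\t2\t0",
               "S4\t0\t0\t1"), p)
  expect_error(suppressMessages(readGenotypeTable(p)), "missing genotype")
  msgs <- capture_messages(ge <- readGenotypeTable(p, dropMissingSamples = TRUE))
  expect_match(paste(msgs, collapse = " "), "dropping 1 sample")
  expect_equal(ncol(ge), 3L)
  expect_false("S2" %in% colnames(ge))
})

test_that("VCF genotypes map GT calls and fall back to CHROM:POS:REF:ALT ids", {
  vcf <- writeDemoVcf(withr::local_tempfile(fileext = ".vcf"), c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1\t1/0",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0\t0/0"))
  ph <- writeDemoPhenotype(withr::local_tempfile(fileext = ".tsv"))
  ge <- suppressWarnings(suppressMessages(readVcfGenotypes(vcf, ph)))
  expect_setequal(snvIds(ge), c("rs1", "1:200:C:T"))
  expect_equal(unname(genotypes(ge)["rs1", ]), c(0L, 1L, 2L, 1L))
  expect_equal(unname(genotypes(ge)["1:200:C:T", ]), rep(0L, 4))
  expect_equal(nCases(ge), 2L)
})

test_that("VCF reader enforces bi-allelic records and phenotype coverage", {
  vcf <- writeDemoVcf(withr::local_tempfile(fileext = ".vcf"),
    "1\t100\trs1\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0")
  ph <- writeDemoPhenotype(withr::local_tempfile(fileext = ".tsv"))
  expect_error(suppressWarnings(readVcfGenotypes(vcf, ph)), "multi-allelic")

  vcf2 <- writeDemoVcf(withr::local_tempfile(fileext = ".vcf"),
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0")
  ph2 <- writeDemoPhenotype(withr::local_tempfile(fileext = ".tsv"),
                            samples = paste0("S", 1:3), status = c(1, 1, 0))
  expect_error(suppressWarnings(readVcfGenotypes(vcf2, ph2)),
               "absent from phenotype")
})

test_that("missing GT follows the drop-or-error policy", {
  vcf <- writeDemoVcf(withr::local_tempfile(fileext = ".vcf"), c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t./.\t1/1\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0\t1/1"))
  ph <- writeDemoPhenotype(withr::local_tempfile(fileext = ".tsv"))
  expect_error(suppressWarnings(suppressMessages(readVcfGenotypes(vcf, ph))),
               "missing GT")
  ge <- suppressWarnings(suppressMessages(
    readVcfGenotypes(vcf, ph, dropMissingSamples = TRUE)))
  expect_equal(ncol(ge), 3L)
  expect_false("S2" %in% colnames(ge))
})

test_that("encoding packs genotypes two bits per byte with shifted copies", {
  ge <- randomGenotypeExperiment(5, 13, 11, seed = 42)
  enc <- encodeCohorts(ge)
  expect_equal(cohortSize(enc$case), 13L)
  expect_equal(cohortSize(enc$control), 11L)

  # stated byte values
  g1 <- GenotypeExperiment(matrix(c(2L, 0L), 2, 1,
                                  dimnames = list(c("S1", "S2"), "A")),
                           phenotype = c(1, 0))
  e1 <- encodeCohorts(g1)
  expect_identical(as.integer(e1$case@shifts[["0"]][1, 1]), 2L)    # 0b00000010
  expect_identical(as.integer(e1$case@shifts[["2"]][1, 1]), 8L)    # 0b00001000
  expect_true(all(sapply(e1$control@shifts, function(s) all(s == as.raw(0)))))

  # round trip: decoding shift-0 bytes reproduces the genotype matrix
  g <- genotypes(ge)
  isCase <- phenotype(ge) == "case"
  expect_identical(decodeCohort(enc$case), t(g[, isCase]))
  expect_identical(decodeCohort(enc$control), t(g[, !isCase]))

  # cohort split is a partition of the samples
  expect_equal(nrow(decodeCohort(enc$case)) + nrow(decodeCohort(enc$control)),
               ncol(ge))
  expect_length(intersect(rownames(decodeCohort(enc$case)),
                          rownames(decodeCohort(enc$control))), 0)

  # shifted copies are exactly shift-0 << k
  for (k in c(2L, 4L, 6L))
    expect_identical(as.integer(enc$case@shifts[[as.character(k)]]),
                     bitwShiftL(as.integer(enc$case@shifts[["0"]]), k))
})

test_that("construction validates codes, ids and phenotype", {
  g <- matrix(c(0L, 3L), 1, 2, dimnames = list("S1", c("A", "B")))
  expect_error(GenotypeExperiment(g, phenotype = 1), "0,1,2")
  g2 <- matrix(0L, 2, 2, dimnames = list(c("S1", "S2"), c("A", "A")))
  expect_error(GenotypeExperiment(g2, phenotype = c(1, 0)), "unique")
  g3 <- matrix(0L, 2, 1, dimnames = list(c("S1", "S2"), "A"))
  expect_error(GenotypeExperiment(g3, phenotype = c(1, 2)), "coded 0")
  expect_error(encodeCohorts(GenotypeExperiment(g3, phenotype = c(1, 1))),
               "non-empty")
})
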