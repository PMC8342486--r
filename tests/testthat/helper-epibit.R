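# Random case/control genotype data for property-style tests.
randomGenotypeExperiment <- function(nSnvs, nCases, nControls, seed = NULL,
                                     mafRange = c(0.1, 0.5)) {
  if (!is.null(seed)) set.seed(seed)
  n <- nCases + nControls
  mafs <- runif(nSnvs, mafRange[1], mafRange[2])
  g <- vapply(mafs, function(f) rbinom(n, 2L, f), integer(n))
  dimnames(g) <- list(paste0("S", seq_len(n)), paste0("V", seq_len(nSnvs)))
  GenotypeExperiment(g, phenotype = rep(c(1, 0), c(nCases, nControls)))
}

# Contingency table built directly from a counts matrix (test scaffolding).
tableFromCounts <- function(counts, ids = paste0("V", seq_len(m))) {
  m <- as.integer(round(log(nrow(counts)) / log(3)))
  epibit:::.newTable(counts, m, ids)
}

writeDemoVcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

writeDemoPhenotype <- function(path, samples = paste0("S", 1:4),
                               status = c(1, 1, 0, 0)) {
  writeLines(c("sample\tphenotype", paste(samples, status, sep = "\t")), path)
  path
}
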