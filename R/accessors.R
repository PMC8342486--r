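#' @describeIn GenotypeExperiment genotype codes, SNVs x samples integer matrix
#' @param x,object a GenotypeExperiment (or the class named in the method)
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("genotypes", "GenotypeExperiment", function(x)
  SummarizedExperiment::assay(x, "genotype"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("phenotype", "GenotypeExperiment", function(x)
  SummarizedExperiment::colData(x)$phenotype)

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("snvIds", function(x) standardGeneric("snvIds"))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("snvIds", "GenotypeExperiment", function(x) rownames(x))

#' @rdname ContingencyTable-class
#' @export
setMethod("snvIds", "ContingencyTable", function(x) x@snvIds)

#' @rdname EncodedCohort-class
#' @export
setMethod("snvIds", "EncodedCohort", function(x) x@snvIds)

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("nCases", "GenotypeExperiment", function(x)
  sum(phenotype(x) == "case"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname GenotypeExperiment-class
#' @export
setMethod("nControls", "GenotypeExperiment", function(x)
  sum(phenotype(x) == "control"))

#' @rdname ContingencyTable-class
#' @param x a ContingencyTable
#' @export
setGeneric("interactionOrder", function(x) standardGeneric("interactionOrder"))

#' @rdname ContingencyTable-class
#' @export
setMethod("interactionOrder", "ContingencyTable", function(x) x@m)

#' @rdname ContingencyTable-class
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "ContingencyTable", function(object, ...) object@counts)

#' @rdname EncodedCohort-class
#' @param x an EncodedCohort
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' @rdname EncodedCohort-class
#' @export
setMethod("cohortSize", "EncodedCohort", function(x) x@s)

#' @rdname NullDistribution-class
#' @param x a NullDistribution
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname NullDistribution-class
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)

#' @rdname SimulatedDataset-class
#' @param x a SimulatedDataset
#' @export
setGeneric("truthTuples", function(x) standardGeneric("truthTuples"))

#' @rdname SimulatedDataset-class
#' @export
setMethod("truthTuples", "SimulatedDataset", function(x) x@truth)

#' @rdname SimulatedDataset-class
#' @export
setGeneric("simData", function(x) standardGeneric("simData"))

#' @rdname SimulatedDataset-class
#' @export
setMethod("simData", "SimulatedDataset", function(x) x@data)

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", nrow(object), "SNVs x", ncol(object), "samples",
      sprintf("(%d cases, %d controls)\n", nCases(object), nControls(object)))
})

setMethod("show", "EncodedCohort", function(object) {
  cat(sprintf("EncodedCohort '%s': %d samples x %d SNVs, shifts 0/2/4/6\n",
              object@cohort, object@s, length(object@snvIds)))
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: order %d over (%s), n = %d\n",
              object@m, paste(object@snvIds, collapse = ", "),
              sum(object@counts)))
  print(object@counts)
})

setMethod("show", "BetaCache", function(object) {
  cat(sprintf("BetaCache: order %d over %d SNVs (%d stored values)\n",
              object@order, object@n, sum(!is.na(object@values))))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution of %s for (%s): %d permutations (seed %d)\n",
    object@statistic, paste(object@snvIds, collapse = ", "),
    object@nPerm, object@seed))
})

setMethod("show", "PenetranceModel", function(object) {
  cat(sprintf("PenetranceModel '%s': %d-SNV, MAF = %s\n", object@label,
              object@m, paste(signif(object@mafs, 3), collapse = "/")))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset (seed %d): %d truth tuple(s)\n",
              object@seed, length(object@truth)))
  show(object@data)
})
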