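#' @rdname HaplotypeAlignment-class
#' @param x,object a package object
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname HaplotypeAlignment-class
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname HaplotypeFreqTable-class
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))

#' @rdname HaplotypeFreqTable-class
#' @export
setGeneric("hapSequences", function(x) standardGeneric("hapSequences"))

#' Population codes of an object
#' @param x a package object carrying population information
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' Effective migrants per generation (2Nm) of an IM parameter set
#'
#' Returns the derived effective-migrant pair: \code{into_b = 2*Nb*mAB}
#' and \code{into_a = 2*Na*mBA}.
#' @param x an \code{IMParams}
#' @export
setGeneric("effectiveMigrants", function(x) standardGeneric("effectiveMigrants"))

#' Fixation indices of an AMOVA result
#' @param x an \code{AmovaResult}
#' @export
setGeneric("fixationIndices", function(x) standardGeneric("fixationIndices"))

## ---- accessors ----

#' @rdname HaplotypeAlignment-class
#' @export
setMethod("alignmentLength", "HaplotypeAlignment",
          function(x) Biostrings::width(x@sequences)[1])

#' @rdname HaplotypeAlignment-class
#' @export
setMethod("seqIds", "HaplotypeAlignment", function(x) names(x@sequences))

#' @rdname HaplotypeFreqTable-class
#' @export
setMethod("hapCounts", "HaplotypeFreqTable", function(x) x@counts)

#' @rdname HaplotypeFreqTable-class
#' @export
setMethod("hapSequences", "HaplotypeFreqTable", function(x) x@haplotypeSeqs)

#' @rdname popNames
#' @export
setMethod("popNames", "HaplotypeFreqTable", function(x) rownames(x@counts))

#' @rdname popNames
#' @export
setMethod("popNames", "GenotypeMatrix", function(x) levels(x@population))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("lociNames", "GenotypeMatrix", function(x) colnames(x@alleleA))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("alleles", "GenotypeMatrix",
          function(x) list(a = x@alleleA, b = x@alleleB))

#' @rdname effectiveMigrants
#' @export
setMethod("effectiveMigrants", "IMParams", function(x)
  c(into_b = 2 * x@Nb * x@mAB, into_a = 2 * x@Na * x@mBA))

#' @rdname fixationIndices
#' @export
setMethod("fixationIndices", "AmovaResult", function(x) x@indices)

## ---- show methods ----

setMethod("show", "HaplotypeAlignment", function(object) {
  cat(sprintf("HaplotypeAlignment: %d sequences x %d sites\n",
              length(object@sequences), alignmentLength(object)))
})

setMethod("show", "HaplotypeFreqTable", function(object) {
  cat(sprintf("HaplotypeFreqTable: %d populations x %d haplotypes (N = %d)\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci, %d populations, %.1f%% missing\n",
              nrow(object@alleleA), ncol(object@alleleA),
              nlevels(object@population),
              100 * mean(is.na(object@alleleA))))
})

setMethod("show", "IMParams", function(object) {
  mig <- effectiveMigrants(object)
  cat("Isolation-with-migration parameters (demographic units):\n")
  cat(sprintf("  Na = %.4g, Nb = %.4g, Nanc = %.4g individuals\n",
              object@Na, object@Nb, object@Nanc))
  cat(sprintf("  T = %.4g years (generation time %.3g y)\n",
              object@Tsplit, object@generationTime))
  cat(sprintf("  m(a>b) = %.4g, m(b>a) = %.4g per generation (2Nm: %.4g, %.4g)\n",
              object@mAB, object@mBA, mig["into_b"], mig["into_a"]))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA:\n")
  print(object@components, row.names = FALSE)
  idx <- object@indices
  for (nm in names(idx))
    cat(sprintf("  %s = %.4f%s\n", nm, idx[nm],
                if (nm %in% names(object@pValues))
                  sprintf(" (p = %.4g)", object@pValues[nm]) else ""))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "PairwiseStructure", function(object) {
  cat(sprintf("PairwiseStructure (%s): %d populations, Bonferroni alpha = %.6g\n",
              object@kind, nrow(object@index), object@alphaAdjusted))
  print(round(object@index, 4))
})

setMethod("show", "IMPosterior", function(object) {
  cat(sprintf("IMPosterior: %d accepted of %d simulations (tolerance %.3g)\n",
              nrow(object@accepted), object@nSims, object@toleranceQuantile))
  for (nm in names(object@pointEstimates))
    cat(sprintf("  %s: mode %.4g, 90%% HPD [%.4g, %.4g]\n", nm,
                object@pointEstimates[nm], object@hpdLower[nm], object@hpdUpper[nm]))
})

setMethod("show", "ConnectivityComparison", function(object) {
  cat(sprintf("ConnectivityComparison: %d pairs, r = %.4f (p = %.4g), %.0f%% below unity\n",
              object@nPairs, object@r, object@p, 100 * object@fracBelowUnity))
})

setMethod("show", "SimulatedDataset", function(object) {
  nseq <- if (is(object@alignment, "HaplotypeAlignment"))
    length(object@alignment@sequences) else 0L
  ngen <- if (is(object@genotypes, "GenotypeMatrix"))
    nrow(object@genotypes@alleleA) else 0L
  cat(sprintf("SimulatedDataset: %d sequences, %d genotyped individuals (seed %d)\n",
              nseq, ngen, object@seed))
})
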