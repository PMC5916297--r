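#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom stats cmdscale cor pt sd median quantile density ks.test rbinom
#'   rmultinom runif setNames var
#' @importFrom utils read.csv write.csv write.table read.table head
#' @useDynLib kelpconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ALIGN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Aligned haploid sequences
#'
#' Container for an alignment of equal-length haploid locus sequences
#' (here: a 623 bp mitochondrial COI fragment), wrapping a
#' \link[Biostrings]{DNAStringSet}. All records must have the same width,
#' unique ids, and width > 0.
#'
#' @slot sequences a \code{DNAStringSet}; names are record ids.
#' @export
setClass("HaplotypeAlignment", slots = c(sequences = "DNAStringSet"))

setValidity("HaplotypeAlignment", function(object) {
  s <- object@sequences
  if (length(s) == 0L) return("alignment must contain at least one record")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return("all sequences must have equal length")
  if (w[1] <= 0L) return("alignment length must be > 0")
  ids <- names(s)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("every record needs an id")
  if (anyDuplicated(ids)) return("record ids must be unique")
  chars <- unique(strsplit(paste(as.character(s), collapse = ""), "")[[1]])
  if (!all(chars %in% ALIGN_ALPHABET))
    return("sequences restricted to alphabet {A,C,G,T,N,-}")
  TRUE
})

#' Per-population haplotype frequency table
#'
#' Counts of each haplotype in each population, the unit of all
#' sequence-based statistics. Row sums are the per-population sample
#' sizes N; column labels are haplotype labels assigned in order of
#' first appearance (a, b, c, ...).
#'
#' @slot counts integer matrix, populations x haplotypes.
#' @slot haplotypeSeqs named character vector mapping haplotype label to
#'   its sequence (may be empty when the table was built from counts only).
#' @export
setClass("HaplotypeFreqTable",
         slots = c(counts = "matrix", haplotypeSeqs = "character"))

setValidity("HaplotypeFreqTable", function(object) {
  cts <- object@counts
  if (!is.numeric(cts)) return("counts must be numeric")
  if (any(cts < 0) || any(cts != round(cts))) return("counts must be non-negative integers")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    return("counts must carry population rownames and haplotype colnames")
  if (anyDuplicated(rownames(cts))) return("population codes must be unique")
  if (anyDuplicated(colnames(cts))) return("haplotype labels must be unique")
  if (any(colSums(cts) == 0)) return("every haplotype must be observed in some population")
  if (length(object@haplotypeSeqs)) {
    if (!all(colnames(cts) %in% names(object@haplotypeSeqs)))
      return("haplotypeSeqs must cover all haplotype labels")
    if (length(unique(nchar(object@haplotypeSeqs))) != 1L)
      return("haplotype sequences must have equal length")
  }
  TRUE
})

#' Diploid microsatellite genotype matrix
#'
#' Individuals x loci diploid calls, stored as two parallel integer
#' matrices (one per allele slot). Alleles are raw integers (fragment
#' sizes or repeat counts); \code{NA} is the single reserved missing
#' token regardless of input dialect. A locus call is either fully
#' present or fully missing.
#'
#' @slot alleleA,alleleB integer matrices (individuals x loci).
#' @slot population factor of population codes, one per individual.
#' @export
setClass("GenotypeMatrix",
         slots = c(alleleA = "matrix", alleleB = "matrix",
                   population = "factor"))

setValidity("GenotypeMatrix", function(object) {
  a <- object@alleleA; b <- object@alleleB
  if (!identical(dim(a), dim(b))) return("allele matrices must share dimensions")
  if (nrow(a) != length(object@population))
    return("one population code per individual required")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    return("unique individual ids required as rownames")
  if (is.null(colnames(a))) return("locus names required as colnames")
  if (!identical(is.na(a), is.na(b)))
    return("a locus call must be fully present or fully missing (both allele slots)")
  if (any(a[!is.na(a)] <= 0) || any(b[!is.na(b)] <= 0))
    return("allele integers must be > 0 when present")
  TRUE
})

#' Isolation-with-migration model parameters (demographic units)
#'
#' The six-parameter two-population IM model: extant effective sizes
#' \code{Na}, \code{Nb}, ancestral size \code{Nanc} (individuals), split
#' time \code{Tsplit} (years; generations = years / generationTime), and
#' forward-in-time per-generation migration fractions \code{mAB} (a to b)
#' and \code{mBA} (b to a). Effective migrants per generation are
#' \code{2*Nb*mAB} into b and \code{2*Na*mBA} into a (see
#' \code{\link{effectiveMigrants}}).
#'
#' @slot Na,Nb,Nanc,Tsplit,mAB,mBA,generationTime numeric scalars.
#' @export
setClass("IMParams",
         slots = c(Na = "numeric", Nb = "numeric", Nanc = "numeric",
                   Tsplit = "numeric", mAB = "numeric", mBA = "numeric",
                   generationTime = "numeric"))

setValidity("IMParams", function(object) {
  v <- c(object@Na, object@Nb, object@Nanc, object@Tsplit,
         object@mAB, object@mBA, object@generationTime)
  if (length(v) != 7L || anyNA(v)) return("all seven parameters must be scalar and non-missing")
  if (any(v < 0)) return("all parameters must be >= 0")
  if (object@generationTime <= 0) return("generationTime must be > 0")
  TRUE
})

#' AMOVA result
#'
#' Method-of-moments variance components from a (two- or three-level)
#' analysis of molecular variance, per-component percentages of total
#' molecular variance, fixation indices, and permutation p-values.
#' Negative component estimates are retained (not truncated) in index
#' computation.
#'
#' @slot components data.frame with columns component, df, SS, variance,
#'   percent.
#' @slot indices named numeric vector (subset of PhiST, FST, FIS, FIT).
#' @slot pValues named numeric vector of permutation p-values.
#' @slot flags character vector of degeneracy notices (e.g., monomorphic
#'   data), empty when clean.
#' @export
setClass("AmovaResult",
         slots = c(components = "data.frame", indices = "numeric",
                   pValues = "numeric", flags = "character"))

setValidity("AmovaResult", function(object) {
  need <- c("component", "df", "SS", "variance", "percent")
  if (!all(need %in% names(object@components)))
    return("components must have columns component, df, SS, variance, percent")
  p <- object@pValues
  if (length(p) && any(!is.na(p) & (p < 0 | p > 1)))
    return("p-values must lie in [0,1]")
  TRUE
})

#' Pairwise population structure
#'
#' Pairwise fixation indices with permutation p-values and the
#' Bonferroni-adjusted significance call (alpha divided by the number of
#' pairwise tests).
#'
#' @slot index symmetric numeric matrix of pairwise Phi_ST or F_ST.
#' @slot p symmetric matrix of permutation p-values (diagonal NA).
#' @slot alphaAdjusted Bonferroni threshold 0.05 / n pairs.
#' @slot significant logical matrix, p < alphaAdjusted.
#' @slot kind "haplotypic" or "genotypic".
#' @export
setClass("PairwiseStructure",
         slots = c(index = "matrix", p = "matrix", alphaAdjusted = "numeric",
                   significant = "matrix", kind = "character"))

setValidity("PairwiseStructure", function(object) {
  if (!isSymmetric(unname(object@index), tol = 1e-12)) return("index matrix must be symmetric")
  pv <- object@p[upper.tri(object@p)]
  if (any(!is.na(pv) & (pv < 0 | pv > 1))) return("p-values must lie in [0,1]")
  TRUE
})

#' ABC posterior for IM parameters
#'
#' Accepted rejection-ABC draws with distances, per-parameter marginal
#' point estimates (weighted-KDE mode) and 90% highest-density intervals.
#'
#' @slot accepted data.frame of accepted parameter draws plus a
#'   \code{distance} column.
#' @slot pointEstimates,hpdLower,hpdUpper named numeric vectors.
#' @slot nSims,toleranceQuantile,seed numeric scalars.
#' @export
setClass("IMPosterior",
         slots = c(accepted = "data.frame", pointEstimates = "numeric",
                   hpdLower = "numeric", hpdUpper = "numeric",
                   nSims = "numeric", toleranceQuantile = "numeric",
                   seed = "numeric"))

setValidity("IMPosterior", function(object) {
  if (nrow(object@accepted) < 1L) return("empty acceptance set")
  nm <- names(object@pointEstimates)
  if (!all(nm %in% names(object@accepted)))
    return("point estimates must correspond to accepted-draw columns")
  TRUE
})

#' Equilibrium vs nonequilibrium connectivity comparison
#'
#' Paired migration estimates per population pair: \code{eqNm} from the
#' Wright island model inversion of pairwise F_ST, and \code{noneqM},
#' the mean of the two directional coalescent migration estimates.
#' Carries the Pearson correlation with its two-tailed t-test p-value,
#' the fraction of pairs whose coalescent estimate falls below the
#' equilibrium estimate, and the least-squares regression line.
#'
#' @slot pairs data.frame with columns pair, eqNm, noneqM.
#' @slot r,p,nPairs,fracBelowUnity,slope,intercept numeric scalars.
#' @export
setClass("ConnectivityComparison",
         slots = c(pairs = "data.frame", r = "numeric", p = "numeric",
                   nPairs = "numeric", fracBelowUnity = "numeric",
                   slope = "numeric", intercept = "numeric"))

setValidity("ConnectivityComparison", function(object) {
  if (!all(c("pair", "eqNm", "noneqM") %in% names(object@pairs)))
    return("pairs needs columns pair, eqNm, noneqM")
  if (length(object@r) && !is.na(object@r) && abs(object@r) > 1 + 1e-12)
    return("r must lie in [-1, 1]")
  if (object@nPairs != nrow(object@pairs)) return("nPairs must match pairs")
  TRUE
})

#' Simulated two-or-more-deme dataset
#'
#' Output of the structured-coalescent simulator: a haploid-locus
#' alignment with its population map, a diploid microsatellite genotype
#' matrix, the generating parameters, and the seed.
#'
#' @slot alignment a \code{HaplotypeAlignment} (or NULL-like empty set).
#' @slot populationOf named character: record id -> population code.
#' @slot genotypes a \code{GenotypeMatrix} (may have 0 loci).
#' @slot trueParams list of the generating parameters.
#' @slot seed numeric.
#' @export
setClass("SimulatedDataset",
         slots = c(alignment = "ANY", populationOf = "character",
                   genotypes = "ANY", trueParams = "list", seed = "numeric"))
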