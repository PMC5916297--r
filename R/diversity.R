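## Per-population diversity statistics and sequence distances.
##
## Both diversity estimators carry the unbiased n/(n-1) correction; the
## standard errors are Nei's (1987) sampling formulas. Distances exclude
## unresolved sites (N, -) pairwise.

#' Unbiased haplotype (gene) diversity with Nei's standard error
#'
#' \eqn{h = n(1 - \sum p_i^2)/(n-1)} with sampling variance
#' \eqn{V = \frac{2}{n(n-1)}\{2(n-2)[\sum p^3 - (\sum p^2)^2] + \sum p^2 -
#' (\sum p^2)^2\}}.
#'
#' @param counts positive integer haplotype counts for one population
#' @return named numeric: \code{h}, \code{se}
#' @examples
#' haplotypeDiversity(c(2, 1))   # h = 0.6667, se = 0.3143
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("domain error: empty counts")
  n <- sum(counts)
  if (n < 2) stop("domain error: need n >= 2")
  p <- counts / n
  sp2 <- sum(p^2); sp3 <- sum(p^3)
  h <- n * (1 - sp2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  c(h = h, se = sqrt(max(v, 0)))
}

#' Unbiased nucleotide diversity per site with Nei's standard error
#'
#' \eqn{\pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j d_{ij} / L} where
#' \eqn{d_{ij}} is the substitution count between haplotypes i and j and
#' L the locus length. The standard error combines Nei's stochastic and
#' sampling terms:
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param counts haplotype counts for one population (aligned with the
#'   rows of \code{hapDistances})
#' @param hapDistances symmetric matrix of substitution counts between
#'   haplotypes
#' @param L locus length in sites (> 0)
#' @return named numeric: \code{pi}, \code{se}
#' @export
nucleotideDiversity <- function(counts, hapDistances, L) {
  if (L <= 0) stop("domain error: L must be > 0")
  keep <- counts > 0
  counts <- counts[keep]
  D <- as.matrix(hapDistances)[keep, keep, drop = FALSE]
  n <- sum(counts)
  if (n < 2) stop("domain error: need n >= 2")
  p <- counts / n
  L <- unname(L)
  pi_raw <- unname(n / (n - 1) * sum(outer(p, p) * D) / L)  # outer counts (i,j) and (j,i): 2*p_i*p_j*d
  v <- (n + 1) / (3 * (n - 1) * L) * pi_raw +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_raw^2
  c(pi = pi_raw, se = sqrt(max(v, 0)))
}

#' Proportion of differing sites between two aligned sequences
#'
#' Sites where either sequence is unresolved (N or -) are excluded
#' pairwise; at least one mutually resolved site is required.
#'
#' @param seqA,seqB character sequences of equal length
#' @return p-distance in [0, 1]
#' @examples
#' pDistance("ACGT", "ACGA")   # 0.25
#' @export
pDistance <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1]]; b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b)) stop("alignment error: unequal lengths")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("domain error: no mutually resolved sites")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise substitution counts among haplotype sequences
#'
#' Integer Hamming distances on mutually resolved sites; symmetric with a
#' zero diagonal.
#'
#' @param sequences named character vector of equal-length sequences
#' @return symmetric integer matrix with the sequence names as labels
#' @export
pairwiseHamming <- function(sequences) {
  if (length(unique(nchar(sequences))) > 1L)
    stop("alignment error: unequal lengths")
  n <- length(sequences)
  labs <- names(sequences)
  if (is.null(labs)) labs <- paste0("h", seq_len(n))
  D <- matrix(0L, n, n, dimnames = list(labs, labs))
  if (n < 2) return(D)
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  res <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- res[i, ] & res[j, ]
    D[i, j] <- D[j, i] <- sum(mat[i, ok] != mat[j, ok])
  }
  D
}

#' Per-population diversity table
#'
#' One row per population: sample size N, haplotype count Nh, nucleotide
#' diversity with SE, haplotype diversity with SE. Monomorphic
#' populations report 0 +- 0 for both.
#'
#' @param freqTable a \code{HaplotypeFreqTable} with sequences attached
#'   (or supply \code{hapDistances})
#' @param L locus length in sites; defaults to the attached sequence length
#' @param hapDistances optional precomputed substitution-count matrix
#' @return data.frame mirroring a summary diversity table
#' @export
diversityTable <- function(freqTable, L = NULL, hapDistances = NULL) {
  cts <- hapCounts(freqTable)
  if (is.null(hapDistances)) {
    seqs <- hapSequences(freqTable)
    if (!length(seqs)) stop("need haplotype sequences or hapDistances")
    hapDistances <- pairwiseHamming(seqs[colnames(cts)])
    if (is.null(L)) L <- nchar(seqs[1])
  }
  if (is.null(L)) stop("L must be supplied when using precomputed distances")
  rows <- lapply(rownames(cts), function(p) {
    cc <- cts[p, ]
    n <- sum(cc)
    hd <- haplotypeDiversity(cc)
    pd <- nucleotideDiversity(cc, hapDistances, L)
    data.frame(population = p, N = n, Nh = sum(cc > 0),
               pi = unname(pd["pi"]), pi_se = unname(pd["se"]),
               h = unname(hd["h"]), h_se = unname(hd["se"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
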