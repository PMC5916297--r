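## Distance-based analysis of molecular variance (AMOVA), pairwise
## structure with Bonferroni correction, individual genetic distances and
## principal coordinates analysis.
##
## Variance components follow the standard method-of-moments
## sums-of-squared-distances equations; negative component estimates are
## retained (not truncated) when forming fixation indices. Permutation
## p-values use the +1 correction: p = (#permuted >= observed + 1)/(B + 1).

## ---- internal: haplotypic (two-level) components from a counts matrix ----
## countsByPop: populations x haplotypes; D: squared-distance matrix
## (substitution counts serve as squared Euclidean distances, the usual
## pairwise-difference convention).
phiComponents <- function(countsByPop, D) {
  n_p <- rowSums(countsByPop)
  keep <- n_p > 0
  countsByPop <- countsByPop[keep, , drop = FALSE]
  n_p <- n_p[keep]
  P <- nrow(countsByPop); N <- sum(n_p)
  tot <- colSums(countsByPop)
  ssd_t <- as.numeric(tot %*% D %*% tot) / (2 * N)
  ssd_w <- sum(vapply(seq_len(P), function(p) {
    cp <- countsByPop[p, ]
    as.numeric(cp %*% D %*% cp) / (2 * n_p[p])
  }, numeric(1)))
  ssd_a <- ssd_t - ssd_w
  df_a <- P - 1; df_w <- N - P
  sigma_w <- ssd_w / df_w
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ssd_a / df_a - sigma_w) / n_c
  list(ssd_a = ssd_a, ssd_w = ssd_w, df_a = df_a, df_w = df_w,
       sigma_a = sigma_a, sigma_w = sigma_w,
       phi = sigma_a / (sigma_a + sigma_w))
}

## tabulate individuals (haplotype index + population index) into a counts matrix
tabulateByPop <- function(popIdx, hapIdx, P, H) {
  matrix(tabulate((hapIdx - 1L) * P + popIdx, nbins = P * H), nrow = P, ncol = H)
}

#' Haplotypic AMOVA (two levels) with permutation test
#'
#' Partitions squared-distance variation among vs within populations;
#' Phi_ST is the among-population proportion of the total variance. The
#' permutation test reassigns individuals to populations keeping sample
#' sizes fixed.
#'
#' @param freqTable a \code{HaplotypeFreqTable}
#' @param hapDistances symmetric substitution-count matrix over the
#'   table's haplotypes (defaults to Hamming distances of attached
#'   sequences); entries are used as squared distances.
#' @param nPermutations permutation count (default 9999); 0 skips the test.
#' @param seed RNG seed (mandatory for a reproducible p-value).
#' @return an \code{\linkS4class{AmovaResult}} with index \code{PhiST}
#' @export
amovaHaplotypic <- function(freqTable, hapDistances = NULL,
                            nPermutations = 9999L, seed) {
  cts <- hapCounts(freqTable)
  if (nrow(cts) < 2L) stop("domain error: need >= 2 populations")
  if (any(rowSums(cts) < 1)) stop("domain error: population with n < 1")
  if (is.null(hapDistances)) {
    seqs <- hapSequences(freqTable)
    if (!length(seqs)) stop("need haplotype sequences or hapDistances")
    hapDistances <- pairwiseHamming(seqs[colnames(cts)])
  }
  D <- as.matrix(hapDistances)[colnames(cts), colnames(cts), drop = FALSE]
  comp <- phiComponents(cts, D)
  flags <- character(0)
  if (!is.finite(comp$phi)) flags <- "monomorphic data: Phi_ST undefined"

  pval <- NA_real_
  if (nPermutations > 0 && is.finite(comp$phi)) {
    if (missing(seed)) stop("seed is required when permuting")
    set.seed(seed)
    P <- nrow(cts); H <- ncol(cts)
    ind <- expandHaplotypes(freqTable)
    hapIdx <- match(ind$haplotype, colnames(cts))
    popIdx <- match(ind$population, rownames(cts))
    ge <- 0L
    for (b in seq_len(nPermutations)) {
      perm <- sample(popIdx)
      phi_b <- phiComponents(tabulateByPop(perm, hapIdx, P, H), D)$phi
      if (is.finite(phi_b) && phi_b >= comp$phi - 1e-12) ge <- ge + 1L
    }
    pval <- (ge + 1) / (nPermutations + 1)
  }
  total <- comp$sigma_a + comp$sigma_w
  components <- data.frame(
    component = c("among populations", "within populations"),
    df = c(comp$df_a, comp$df_w),
    SS = c(comp$ssd_a, comp$ssd_w),
    variance = c(comp$sigma_a, comp$sigma_w),
    percent = 100 * c(comp$sigma_a, comp$sigma_w) / total,
    stringsAsFactors = FALSE)
  new("AmovaResult", components = components,
      indices = c(PhiST = comp$phi),
      pValues = c(PhiST = pval), flags = flags)
}

## ---- internal: per-locus three-level components for diploid data ----
## popIdx: integer per individual; a, b: allele vectors (NA = missing)
locusComponents <- function(popIdx, a, b) {
  ok <- !is.na(a)
  if (!any(ok)) return(NULL)
  popIdx <- popIdx[ok]; a <- a[ok]; b <- b[ok]
  pops <- sort(unique(popIdx))
  if (length(pops) < 2L) return(NULL)
  n_p <- as.numeric(table(factor(popIdx, levels = pops)))
  N <- sum(n_p); P <- length(pops)
  lev <- sort(unique(c(a, b)))
  K <- length(lev)
  ai <- match(a, lev); bi <- match(b, lev)
  pi2 <- match(popIdx, pops)
  cnt <- matrix(tabulate((ai - 1L) * P + pi2, nbins = P * K), P, K) +
         matrix(tabulate((bi - 1L) * P + pi2, nbins = P * K), P, K)
  g_p <- 2 * n_p; G <- 2 * N
  ctot <- colSums(cnt)
  ssd_t <- (choose(G, 2) - sum(choose(ctot, 2))) / G
  ssd_wp <- sum((choose(g_p, 2) - rowSums(choose(cnt, 2))) / g_p)
  n_het <- sum(ai != bi)
  ssd_wi <- n_het / 2
  ssd_ai <- ssd_wp - ssd_wi
  ssd_ap <- ssd_t - ssd_wp
  df_ap <- P - 1; df_ai <- N - P; df_wi <- N
  sigma_c <- ssd_wi / df_wi
  sigma_b <- (ssd_ai / df_ai - sigma_c) / 2
  n_c <- (G - sum(g_p^2) / G) / (P - 1)
  sigma_a <- (ssd_ap / df_ap - sigma_c - 2 * sigma_b) / n_c
  list(ss = c(ssd_ap, ssd_ai, ssd_wi), df = c(df_ap, df_ai, df_wi),
       sigma = c(sigma_a, sigma_b, sigma_c), monomorphic = (K == 1L))
}

genotypicComponents <- function(popIdx, A, B) {
  per_locus <- lapply(seq_len(ncol(A)), function(l)
    locusComponents(popIdx, A[, l], B[, l]))
  per_locus <- Filter(Negate(is.null), per_locus)
  if (!length(per_locus)) return(NULL)
  ss <- Reduce(`+`, lapply(per_locus, `[[`, "ss"))
  df <- Reduce(`+`, lapply(per_locus, `[[`, "df"))
  sigma <- Reduce(`+`, lapply(per_locus, `[[`, "sigma"))
  list(ss = ss, df = df, sigma = sigma,
       all_monomorphic = all(vapply(per_locus, `[[`, logical(1), "monomorphic")))
}

indicesFromSigma <- function(sigma) {
  tot <- sum(sigma)
  c(FST = sigma[1] / tot,
    FIS = sigma[2] / (sigma[2] + sigma[3]),
    FIT = (sigma[1] + sigma[2]) / tot)
}

#' Genotypic AMOVA (three levels) with per-index permutation tests
#'
#' Partitions diploid microsatellite variation into among-population,
#' among-individual-within-population and within-individual components,
#' summed over loci (individuals missing a locus are dropped from that
#' locus only). F_ST, F_IS and F_IT are component ratios; the identity
#' \eqn{(1-F_{IT}) = (1-F_{IS})(1-F_{ST})} holds by construction.
#'
#' Permutation schemes: F_ST permutes individuals among populations;
#' F_IS permutes allele copies among individuals within populations;
#' F_IT permutes allele copies globally.
#'
#' A fully monomorphic dataset yields a flagged result (indices NA), not
#' an exception.
#'
#' @param genotypes a \code{GenotypeMatrix} with >= 2 populations
#' @param nPermutations permutation count (default 9999); 0 skips tests.
#' @param seed RNG seed, required when permuting.
#' @return an \code{\linkS4class{AmovaResult}} with indices FST, FIS, FIT
#' @export
amovaGenotypic <- function(genotypes, nPermutations = 9999L, seed) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  A <- genotypes@alleleA; B <- genotypes@alleleB
  popIdx <- as.integer(genotypes@population)
  if (length(unique(popIdx)) < 2L) stop("domain error: need >= 2 populations")
  comp <- genotypicComponents(popIdx, A, B)
  labels <- c("among populations", "among individuals within populations",
              "within individuals")
  if (is.null(comp) || comp$all_monomorphic) {
    components <- data.frame(component = labels, df = NA_real_, SS = NA_real_,
                             variance = NA_real_, percent = NA_real_,
                             stringsAsFactors = FALSE)
    return(new("AmovaResult", components = components,
               indices = c(FST = NA_real_, FIS = NA_real_, FIT = NA_real_),
               pValues = numeric(0),
               flags = "monomorphic dataset: indices undefined"))
  }
  idx <- indicesFromSigma(comp$sigma)
  flags <- character(0)
  if (!all(is.finite(idx))) flags <- "zero-variance component: some indices undefined"

  pv <- c(FST = NA_real_, FIS = NA_real_, FIT = NA_real_)
  if (nPermutations > 0) {
    if (missing(seed)) stop("seed is required when permuting")
    set.seed(seed)
    nInd <- nrow(A)
    geFST <- geFIS <- geFIT <- 0L
    for (bb in seq_len(nPermutations)) {
      ## F_ST: individuals among populations
      if (is.finite(idx["FST"])) {
        cb <- genotypicComponents(sample(popIdx), A, B)
        v <- indicesFromSigma(cb$sigma)["FST"]
        if (is.finite(v) && v >= idx["FST"] - 1e-12) geFST <- geFST + 1L
      }
      ## F_IS: alleles among individuals within populations
      if (is.finite(idx["FIS"])) {
        A2 <- A; B2 <- B
        for (p in unique(popIdx)) {
          sel <- which(popIdx == p)
          for (l in seq_len(ncol(A))) {
            here <- sel[!is.na(A[sel, l])]
            if (length(here) > 1L) {
              pool <- sample(c(A[here, l], B[here, l]))
              A2[here, l] <- pool[seq_along(here)]
              B2[here, l] <- pool[length(here) + seq_along(here)]
            }
          }
        }
        cb <- genotypicComponents(popIdx, A2, B2)
        v <- indicesFromSigma(cb$sigma)["FIS"]
        if (is.finite(v) && v >= idx["FIS"] - 1e-12) geFIS <- geFIS + 1L
      }
      ## F_IT: alleles globally
      if (is.finite(idx["FIT"])) {
        A3 <- A; B3 <- B
        for (l in seq_len(ncol(A))) {
          here <- which(!is.na(A[, l]))
          if (length(here) > 1L) {
            pool <- sample(c(A[here, l], B[here, l]))
            A3[here, l] <- pool[seq_along(here)]
            B3[here, l] <- pool[length(here) + seq_along(here)]
          }
        }
        cb <- genotypicComponents(popIdx, A3, B3)
        v <- indicesFromSigma(cb$sigma)["FIT"]
        if (is.finite(v) && v >= idx["FIT"] - 1e-12) geFIT <- geFIT + 1L
      }
    }
    pv <- c(FST = (geFST + 1) / (nPermutations + 1),
            FIS = (geFIS + 1) / (nPermutations + 1),
            FIT = (geFIT + 1) / (nPermutations + 1))
    pv[!is.finite(idx)] <- NA_real_
  }
  components <- data.frame(component = labels, df = comp$df, SS = comp$ss,
                           variance = comp$sigma,
                           percent = 100 * comp$sigma / sum(comp$sigma),
                           stringsAsFactors = FALSE)
  new("AmovaResult", components = components, indices = idx,
      pValues = pv, flags = flags)
}

#' Pairwise population structure with Bonferroni correction
#'
#' Runs the appropriate AMOVA independently for every population pair and
#' assembles the index and p-value matrices. The Bonferroni-adjusted
#' threshold is 0.05 divided by the number of pairs.
#'
#' @param data a \code{HaplotypeFreqTable} (kind "haplotypic") or
#'   \code{GenotypeMatrix} (kind "genotypic")
#' @param kind "haplotypic" or "genotypic"
#' @param nPermutations permutations per pair
#' @param seed RNG seed
#' @param hapDistances optional distance matrix for the haplotypic case
#' @param alpha family-wise significance level (default 0.05)
#' @return a \code{\linkS4class{PairwiseStructure}}
#' @export
pairwiseStructure <- function(data, kind = c("haplotypic", "genotypic"),
                              nPermutations = 999L, seed,
                              hapDistances = NULL, alpha = 0.05) {
  kind <- match.arg(kind)
  pops <- popNames(data)
  k <- length(pops)
  if (k < 2L) stop("domain error: need >= 2 populations")
  nPairs <- k * (k - 1) / 2
  idxM <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pM <- idxM
  diag(idxM) <- 0
  pair_i <- 0L
  if (missing(seed)) seed <- 1L
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pair_i <- pair_i + 1L
    if (kind == "haplotypic") {
      cts <- hapCounts(data)[c(i, j), , drop = FALSE]
      keep <- colSums(cts) > 0
      sub <- new("HaplotypeFreqTable", counts = cts[, keep, drop = FALSE],
                 haplotypeSeqs = if (length(hapSequences(data)))
                   hapSequences(data)[keep] else character(0))
      D <- if (!is.null(hapDistances))
        as.matrix(hapDistances)[keep, keep, drop = FALSE] else NULL
      res <- amovaHaplotypic(sub, D, nPermutations, seed = seed + pair_i)
      idxM[i, j] <- idxM[j, i] <- res@indices["PhiST"]
      pM[i, j] <- pM[j, i] <- res@pValues["PhiST"]
    } else {
      sel <- genotypes_sel <- which(as.character(data@population) %in% pops[c(i, j)])
      sub <- genotypeMatrix(data@alleleA[sel, , drop = FALSE],
                            data@alleleB[sel, , drop = FALSE],
                            as.character(data@population)[sel])
      res <- amovaGenotypic(sub, nPermutations, seed = seed + pair_i)
      idxM[i, j] <- idxM[j, i] <- res@indices["FST"]
      pM[i, j] <- pM[j, i] <- res@pValues["FST"]
    }
  }
  alphaAdj <- alpha / nPairs
  sig <- !is.na(pM) & pM < alphaAdj
  new("PairwiseStructure", index = idxM, p = pM, alphaAdjusted = alphaAdj,
      significant = sig, kind = kind)
}

#' Squared allele-mismatch distance between diploid individuals
#'
#' Per locus: 0 for identical genotypes, 1 when exactly one allele is
#' shared, 2 when none; summed over loci typed in both individuals.
#' Individuals missing every locus are excluded with a warning.
#'
#' @param genotypes a \code{GenotypeMatrix}
#' @return symmetric numeric matrix (individual x individual)
#' @export
genotypeDistance <- function(genotypes) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  A <- genotypes@alleleA; B <- genotypes@alleleB
  allMissing <- rowSums(!is.na(A)) == 0
  if (any(allMissing)) {
    warning("excluding ", sum(allMissing), " individual(s) with all loci missing")
    A <- A[!allMissing, , drop = FALSE]; B <- B[!allMissing, , drop = FALSE]
  }
  n <- nrow(A)
  D <- matrix(0, n, n, dimnames = list(rownames(A), rownames(A)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(A[i, ]) & !is.na(A[j, ])
    d <- 0
    for (l in which(ok)) {
      gi <- c(A[i, l], B[i, l]); gj <- c(A[j, l], B[j, l])
      shared <- sum(pmin(table(factor(gi, unique(c(gi, gj)))),
                         table(factor(gj, unique(c(gi, gj))))))
      d <- d + (2 - shared)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers \eqn{-\tfrac{1}{2}D^2}, eigendecomposes, and returns
#' coordinates scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues are dropped from the coordinates and reported
#' separately; percent explained is taken over the positive eigenvalues.
#'
#' @param distances symmetric distance matrix
#' @param nAxes requested number of axes (silently truncated to the
#'   positive-eigenvalue rank, with a notice via \code{message})
#' @return list with \code{coordinates}, \code{eigenvalues} (descending,
#'   positive), \code{negativeEigenvalues}, \code{percentExplained}
#' @export
pcoaAnalysis <- function(distances, nAxes = 2L) {
  D <- as.matrix(distances)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  fit <- stats::cmdscale(D, k = max(1L, min(nAxes, n - 1L)), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-9]
  neg <- eig[eig < -1e-9]
  rank <- length(pos)
  if (rank == 0L) {
    coords <- matrix(0, n, max(1L, nAxes),
                     dimnames = list(rownames(D), NULL))
    return(list(coordinates = coords, eigenvalues = numeric(0),
                negativeEigenvalues = neg, percentExplained = numeric(0)))
  }
  keep <- min(nAxes, rank)
  if (keep < nAxes)
    message("pcoa: only ", rank, " positive axes available; truncating")
  coords <- fit$points[, seq_len(keep), drop = FALSE]
  rownames(coords) <- rownames(D)
  list(coordinates = coords,
       eigenvalues = pos,
       negativeEigenvalues = neg,
       percentExplained = 100 * pos / sum(pos))
}
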