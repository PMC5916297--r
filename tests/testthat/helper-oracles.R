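# Independent brute-force oracles used across the suite. These loop over
# individual gene copies / edges explicitly, never reusing the package's
# frequency-based shortcuts.

# Two-level AMOVA components by explicit pairwise squared-distance sums.
# pops: character per individual; hapIdx: haplotype index per individual;
# D: haplotype squared-distance matrix.
bruteAmovaHaplotypic <- function(pops, hapIdx, D) {
  N <- length(pops)
  ssd_of <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) s <- s + D[hapIdx[i], hapIdx[j]]
    s / (2 * length(idx))
  }
  ssd_t <- ssd_of(seq_len(N))
  ssd_w <- sum(vapply(unique(pops), function(p) ssd_of(which(pops == p)),
                      numeric(1)))
  ssd_a <- ssd_t - ssd_w
  P <- length(unique(pops))
  n_p <- as.numeric(table(pops))
  sigma_w <- ssd_w / (N - P)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ssd_a / (P - 1) - sigma_w) / n_c
  list(ssd_a = ssd_a, ssd_w = ssd_w, sigma_a = sigma_a, sigma_w = sigma_w,
       phi = sigma_a / (sigma_a + sigma_w))
}

# Three-level diploid AMOVA components by explicit allele-copy loops for
# a single locus (no missing data), 0/1 allele mismatch distance.
bruteAmovaGenotypic1 <- function(pops, a, b) {
  copies <- c(a, b)
  copyPop <- c(pops, pops)
  copyInd <- c(seq_along(a), seq_along(a))
  ssd_of <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) s <- s + (copies[i] != copies[j])
    s / (2 * length(idx))
  }
  G <- length(copies)
  N <- length(a)
  P <- length(unique(pops))
  ssd_t <- ssd_of(seq_len(G))
  ssd_wp <- sum(vapply(unique(pops), function(p) ssd_of(which(copyPop == p)),
                       numeric(1)))
  ssd_wi <- sum(vapply(seq_len(N), function(i) ssd_of(which(copyInd == i)),
                       numeric(1)))
  ssd_ai <- ssd_wp - ssd_wi
  ssd_ap <- ssd_t - ssd_wp
  sig_c <- ssd_wi / N
  sig_b <- (ssd_ai / (N - P) - sig_c) / 2
  g_p <- 2 * as.numeric(table(pops))
  n_c <- (G - sum(g_p^2) / G) / (P - 1)
  sig_a <- (ssd_ap / (P - 1) - sig_c - 2 * sig_b) / n_c
  list(ss = c(ssd_ap, ssd_ai, ssd_wi), sigma = c(sig_a, sig_b, sig_c))
}

# Exhaustive minimum spanning tree: enumerate all (n-1)-edge subsets.
bruteMstWeight <- function(D) {
  n <- nrow(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  ne <- nrow(idx)
  best <- Inf
  for (sub in utils::combn(ne, n - 1, simplify = FALSE)) {
    # connectivity check via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sub) {
      ri <- find(idx[e, 1]); rj <- find(idx[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(D[idx[sub, , drop = FALSE]]))
  }
  best
}

# Frequency-based F_ST for haploid data (weighted, for the all-distances-
# equal-1 equivalence check): variance components on allele indicators.
freqBasedFst <- function(pops, hapIdx) {
  # identical to two-level AMOVA with D = 1 - identity
  H <- max(hapIdx)
  D <- matrix(1, H, H); diag(D) <- 0
  bruteAmovaHaplotypic(pops, hapIdx, D)$phi
}

# G_ST-style multilocus F_ST (ratio of sums of expected heterozygosities)
gstFromGenotypes <- function(gm) {
  A <- alleles(gm)$a; B <- alleles(gm)$b
  pop <- gm@population
  hs <- ht <- 0
  for (l in seq_len(ncol(A))) {
    g <- c(A[, l], B[, l]); pl <- rep(pop, 2)
    keep <- !is.na(g); g <- g[keep]; pl <- pl[keep]
    f <- table(g) / length(g)
    ht <- ht + 1 - sum(f^2)
    hw <- mean(vapply(levels(pop), function(p) {
      fp <- table(g[pl == p]) / sum(pl == p)
      1 - sum(fp^2)
    }, numeric(1)))
    hs <- hs + hw
  }
  1 - hs / ht
}

toyFreqTable <- function() {
  haplotypeFreqTable(
    matrix(c(4, 2, 0, 0, 2, 4), nrow = 3,
           dimnames = list(c("P1", "P2", "P3"), c("a", "b"))))
}

chainDistances <- function() {
  matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}
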