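test_that("haplotypic AMOVA matches the brute-force sums-of-squares oracle", {
  ft <- toyFreqTable()
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- amovaHaplotypic(ft, D, nPermutations = 0)
  pops <- rep(c("P1", "P2", "P3"), each = 4)
  hapIdx <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  oracle <- bruteAmovaHaplotypic(pops, hapIdx, D)
  expect_equal(res@components$SS[1], oracle$ssd_a, tolerance = 1e-12)
  expect_equal(res@components$SS[2], oracle$ssd_w, tolerance = 1e-12)
  expect_equal(res@components$variance, c(oracle$sigma_a, oracle$sigma_w),
               tolerance = 1e-12)
  expect_equal(unname(res@indices["PhiST"]), oracle$phi, tolerance = 1e-12)
  expect_equal(sum(res@components$percent), 100, tolerance = 0.1)
})

test_that("fixed populations give Phi_ST = 1; identical ones give ~0", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  fixed <- haplotypeFreqTable(matrix(c(8L, 0L, 0L, 8L), 2, 2,
                                     dimnames = list(c("X", "Y"), c("a", "b"))))
  r1 <- amovaHaplotypic(fixed, D, nPermutations = 99, seed = 1)
  expect_equal(unname(r1@indices["PhiST"]), 1)
  expect_lt(unname(r1@pValues["PhiST"]), 0.05)

  same <- haplotypeFreqTable(matrix(c(40L, 40L, 40L, 40L), 2, 2,
                                    dimnames = list(c("X", "Y"), c("a", "b"))))
  r2 <- amovaHaplotypic(same, D, nPermutations = 99, seed = 1)
  expect_lt(abs(unname(r2@indices["PhiST"])), 0.05)
  expect_gt(unname(r2@pValues["PhiST"]), 0.1)
})

test_that("with all pairwise distances 1 the haplotypic AMOVA reduces to frequency F_ST", {
  set.seed(21)
  cts <- matrix(rpois(12, 5) + 1L, 3, 4,
                dimnames = list(c("P1", "P2", "P3"), letters[1:4]))
  ft <- haplotypeFreqTable(cts)
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(D) <- 0
  res <- amovaHaplotypic(ft, D, nPermutations = 0)
  ind <- expandHaplotypes(ft)
  expect_equal(unname(res@indices["PhiST"]),
               freqBasedFst(ind$population, match(ind$haplotype, letters[1:4])),
               tolerance = 1e-12)
})

test_that("genotypic AMOVA matches the explicit allele-copy oracle", {
  # 2 loci, 8 individuals, 2 populations, no missing data
  set.seed(33)
  pops <- rep(c("X", "Y"), each = 4)
  A <- matrix(sample(1:3, 16, TRUE), 8, 2)
  B <- matrix(sample(1:3, 16, TRUE), 8, 2)
  gm <- genotypeMatrix(A, B, pops)
  res <- amovaGenotypic(gm, nPermutations = 0)
  o1 <- bruteAmovaGenotypic1(pops, A[, 1], B[, 1])
  o2 <- bruteAmovaGenotypic1(pops, A[, 2], B[, 2])
  expect_equal(res@components$SS, o1$ss + o2$ss, tolerance = 1e-12)
  expect_equal(res@components$variance, o1$sigma + o2$sigma, tolerance = 1e-12)
  sig <- o1$sigma + o2$sigma
  expect_equal(unname(res@indices["FST"]), sig[1] / sum(sig), tolerance = 1e-12)
  expect_equal(unname(res@indices["FIS"]), sig[2] / (sig[2] + sig[3]),
               tolerance = 1e-12)
})

test_that("genotypic AMOVA trivial regimes: fixed difference and Hardy-Weinberg", {
  # two populations fixed for different alleles, all homozygous
  gm <- genotypeMatrix(matrix(c(1L, 1L, 2L, 2L), 4, 1),
                       matrix(c(1L, 1L, 2L, 2L), 4, 1),
                       c("X", "X", "Y", "Y"))
  r <- amovaGenotypic(gm, nPermutations = 0)
  expect_equal(unname(r@indices["FST"]), 1)
  expect_false(is.finite(r@indices["FIS"]))  # no within-individual variance
  expect_length(r@flags, 1L)

  # Hardy-Weinberg genotypes in two identical populations: F_IS ~ 0
  set.seed(8)
  n <- 300
  A <- matrix(sample(1:4, 2 * n, TRUE), n, 2)
  B <- matrix(sample(1:4, 2 * n, TRUE), n, 2)
  gm2 <- genotypeMatrix(A, B, rep(c("X", "Y"), each = n / 2))
  r2 <- amovaGenotypic(gm2, nPermutations = 0)
  expect_lt(abs(unname(r2@indices["FIS"])), 0.06)
  expect_lt(abs(unname(r2@indices["FST"])), 0.02)
})

test_that("monomorphic genotype data flag rather than error", {
  gm <- genotypeMatrix(matrix(5L, 6, 2), matrix(5L, 6, 2),
                       rep(c("X", "Y"), each = 3))
  r <- amovaGenotypic(gm, nPermutations = 0)
  expect_true(all(!is.finite(r@indices)))
  expect_match(r@flags, "monomorphic")
})

test_that("the fixation-index identity holds on every run", {
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(12:30, 1)
    nl <- sample(2:4, 1)
    A <- matrix(sample(1:4, n * nl, TRUE), n, nl)
    B <- matrix(sample(1:4, n * nl, TRUE), n, nl)
    # impose some structure and inbreeding
    pop <- rep(c("X", "Y", "Z"), length.out = n)
    A[pop == "X", 1] <- 9L
    hom <- sample(n, n %/% 3)
    B[hom, ] <- A[hom, ]
    # sprinkle missing calls
    A[sample(length(A), 3)] <- NA
    r <- amovaGenotypic(genotypeMatrix(A, B, pop), nPermutations = 0)
    i <- r@indices
    if (all(is.finite(i)))
      expect_equal((1 - i[["FIT"]]), (1 - i[["FIS"]]) * (1 - i[["FST"]]),
                   tolerance = 1e-9)
    expect_equal(sum(r@components$percent), 100, tolerance = 0.1)
  }
})

test_that("pairwise structure applies the Bonferroni threshold", {
  # k = 7 populations -> 21 pairs, alpha 0.05/21
  cts <- matrix(rep(c(6L, 2L), 7), 7, 2, byrow = TRUE,
                dimnames = list(paste0("P", 1:7), c("a", "b")))
  ft <- haplotypeFreqTable(cts)
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ps <- pairwiseStructure(ft, "haplotypic", nPermutations = 19, seed = 4,
                          hapDistances = D)
  expect_equal(ps@alphaAdjusted, 0.05 / 21, tolerance = 1e-9)
  # identical populations: nothing significant
  expect_false(any(ps@significant))
  expect_true(isSymmetric(unname(ps@index)))
})

test_that("pairwise ordering matches the underlying differentiation", {
  # two fixed populations plus one intermediate
  cts <- matrix(c(10L, 0L, 5L, 5L, 0L, 10L), 3, 2, byrow = TRUE,
                dimnames = list(c("L", "M", "R"), c("a", "b")))
  ft <- haplotypeFreqTable(cts)
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ps <- pairwiseStructure(ft, "haplotypic", nPermutations = 0, seed = 1,
                          hapDistances = D)
  expect_gt(ps@index["L", "R"], ps@index["L", "M"])
  expect_equal(ps@index["L", "M"], ps@index["M", "R"], tolerance = 1e-12)
})

test_that("genotype distance counts allele mismatches and excludes missing pairs", {
  A <- matrix(c(1L, 1L, 1L, 2L, 3L, 3L), 3, 2, byrow = TRUE)
  B <- matrix(c(1L, 1L, 1L, 2L, 4L, 3L), 3, 2, byrow = TRUE)
  gm <- genotypeMatrix(A, B, rep("P", 3), ids = c("i1", "i2", "i3"))
  D <- genotypeDistance(gm)
  expect_equal(unname(D["i1", "i1"]), 0)
  # i1 {1,1} vs i2 {1,1} locus1 = 0; {1,1} vs {2,2} locus2 = 2
  expect_equal(unname(D["i1", "i2"]), 2)
  # i2 vs i3: locus1 {1,1} vs {3,4} = 2, locus2 {2,2} vs {3,3} = 2
  expect_equal(unname(D["i2", "i3"]), 4)
  # heterozygote vs homozygote sharing one allele -> distance 1
  het <- genotypeMatrix(matrix(c(3L, 3L), 2, 1), matrix(c(4L, 3L), 2, 1),
                        c("P", "P"), ids = c("h1", "h2"))
  expect_equal(unname(genotypeDistance(het)["h1", "h2"]), 1)
  # missing locus excluded pairwise
  A2 <- A; A2[2, 2] <- NA; B2 <- B
  B2[2, 2] <- NA
  gm2 <- genotypeMatrix(A2, B2, rep("P", 3), ids = c("i1", "i2", "i3"))
  expect_equal(unname(genotypeDistance(gm2)["i1", "i2"]), 0)
  expect_warning(genotypeDistance(
    genotypeMatrix(matrix(NA_integer_, 2, 1), matrix(NA_integer_, 2, 1),
                   c("P", "P"))), "all loci missing")
})

test_that("genotype distances satisfy the triangle inequality on small matrices", {
  set.seed(91)
  for (rep in 1:6) {
    n <- 5
    A <- matrix(sample(1:3, n * 3, TRUE), n, 3)
    B <- matrix(sample(1:3, n * 3, TRUE), n, 3)
    D <- genotypeDistance(genotypeMatrix(A, B, rep("P", n)))
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})

test_that("PCoA reconstructs distances and handles degenerate input", {
  D <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  D["x", "y"] <- D["y", "x"] <- 3
  D["x", "z"] <- D["z", "x"] <- 4
  D["y", "z"] <- D["z", "y"] <- 5
  pc <- pcoaAnalysis(D, nAxes = 2)
  rec <- as.matrix(dist(pc$coordinates))
  expect_equal(unname(rec), unname(D), tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_equal(unname(colMeans(pc$coordinates)), c(0, 0), tolerance = 1e-9)
  expect_equal(sum(pc$percentExplained), 100, tolerance = 1e-9)

  # all-zero distances -> all coordinates 0 (cmdscale warns: no positive axes)
  Z <- matrix(0, 4, 4)
  expect_true(all(suppressWarnings(pcoaAnalysis(Z, 2))$coordinates == 0))

  # duplicated individual -> identical coordinates
  D2 <- rbind(cbind(D, dup = D[, "x"]), dup = c(D["x", ], 0))
  pc2 <- pcoaAnalysis(D2, 2)
  expect_equal(pc2$coordinates["x", ], pc2$coordinates["dup", ],
               tolerance = 1e-9)
})

test_that("null permutation p-values are approximately uniform", {
  # haplotypic AMOVA under the null: K-S against U(0,1). Samples are
  # large enough, with enough haplotype classes and generic distances,
  # that permutation ties (which make p conservative) are rare.
  set.seed(63)
  labs <- paste0("h", 1:10)
  D <- matrix(runif(100, 0.5, 3), 10, 10)
  D <- (D + t(D)) / 2; diag(D) <- 0
  dimnames(D) <- list(labs, labs)
  pv <- replicate(200, {
    cts <- t(rmultinom(2, 60, rep(0.1, 10)))
    dimnames(cts) <- list(c("X", "Y"), labs)
    keep <- colSums(cts) > 0
    ft <- haplotypeFreqTable(cts[, keep, drop = FALSE])
    r <- amovaHaplotypic(ft, D[keep, keep, drop = FALSE],
                         nPermutations = 199, seed = sample.int(1e6, 1))
    unname(r@pValues["PhiST"])
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})
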