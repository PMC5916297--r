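test_that("haplotype diversity matches the unbiased estimator with Nei SE", {
  # published diversity values for small kelp samples
  r <- haplotypeDiversity(c(2, 1))
  expect_equal(round(unname(r["h"]), 4), 0.6667)
  expect_equal(round(unname(r["se"]), 4), 0.3143)
  expect_equal(round(unname(haplotypeDiversity(c(12, 1))["h"]), 4), 0.1538)
  expect_equal(round(unname(haplotypeDiversity(c(18, 3, 1))["h"]), 4), 0.3247)
  # monomorphic
  expect_equal(unname(haplotypeDiversity(c(7))), c(0, 0))
  expect_error(haplotypeDiversity(c(1)), "domain error")
  # permutation invariance
  expect_equal(haplotypeDiversity(c(5, 3, 2)), haplotypeDiversity(c(2, 5, 3)))
})

test_that("nucleotide diversity follows the unbiased per-site formula", {
  D1 <- matrix(c(0, 1, 1, 0), 2, 2)
  r <- nucleotideDiversity(c(2, 1), D1, 623)
  expect_equal(unname(r["pi"]), (3 / 2) * (4 / 9) / 623, tolerance = 1e-12)
  expect_equal(unname(r["pi"]), 0.00107, tolerance = 1e-3)
  # monomorphic
  expect_equal(unname(nucleotideDiversity(c(5), matrix(0, 1, 1), 100)["pi"]), 0)
  # two sequences differing at every site -> pi = 1
  L <- 10
  DL <- matrix(c(0, L, L, 0), 2, 2)
  expect_equal(unname(nucleotideDiversity(c(1, 1), DL, L)["pi"]), 1)
  expect_error(nucleotideDiversity(c(2, 1), D1, 0), "domain error")
  # for n = 2, pi equals the p-distance of the two sequences
  sa <- "ACGTACGTAC"; sb <- "ACGAACGTTC"
  D <- pairwiseHamming(c(a = sa, b = sb))
  expect_equal(unname(nucleotideDiversity(c(1, 1), D, 10)["pi"]),
               pDistance(sa, sb))
})

test_that("p-distance excludes unresolved sites pairwise", {
  expect_equal(pDistance("ACGT", "ACGT"), 0)
  expect_equal(pDistance("ACGT", "ACGA"), 0.25)
  expect_equal(pDistance("ACNT", "ACGA"), 1 / 3)
  expect_error(pDistance("NNNN", "ACGT"), "domain error")
  expect_error(pDistance("ACG", "ACGT"), "alignment error")
})

test_that("pairwise Hamming equals the per-site brute-force count", {
  expect_equal(max(pairwiseHamming(c(a = "ACGT", b = "ACGT"))), 0L)
  D <- pairwiseHamming(c(A = "AAAA", B = "AAAT", C = "AATT"))
  expect_equal(unname(D["A", "B"]), 1L)
  expect_equal(unname(D["A", "C"]), 2L)
  set.seed(11)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("h", 1:6)
  D <- pairwiseHamming(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(unname(D[i, j]), sum(mat[i, ] != mat[j, ]))
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0L, 6))
})

test_that("diversity table reproduces the fixture's per-population pattern", {
  fx <- fixtureHaplotypes()
  tab <- diversityTable(fx$freqTable)
  fixed <- tab$population %in% c("SL", "SN", "SF1", "SW")
  expect_true(all(tab$h[fixed] == 0 & tab$pi[fixed] == 0))
  expect_equal(round(tab$h[tab$population == "SS"], 4), 0.6667)
  expect_equal(round(tab$h_se[tab$population == "SS"], 4), 0.3143)
  expect_equal(round(tab$h[tab$population == "SF2"], 4), 0.1538)
  expect_equal(round(tab$h[tab$population == "SD"], 4), 0.3247)
  expect_equal(sum(tab$N), 191)
})
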