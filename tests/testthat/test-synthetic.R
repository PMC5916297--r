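test_that("default design reproduces the study's sampling layout", {
  d <- studyDesign()
  expect_equal(nrow(d$populations), 9)
  expect_equal(sum(d$populations$nSeq), 191)
  expect_equal(sum(d$populations$nGeno), 213)
  ds <- suppressWarnings(generateStudyLike(d, seed = 3))
  expect_equal(length(ds@alignment@sequences), 191)
  expect_equal(nrow(alleles(ds@genotypes)$a), 213)
  expect_equal(nlevels(ds@genotypes@population), 9)
  expect_equal(alignmentLength(ds@alignment), 623)
  expect_equal(ncol(alleles(ds@genotypes)$a), 10)
})

test_that("generation is byte-identical under a fixed seed", {
  d <- studyDesign()
  a <- suppressWarnings(generateStudyLike(d, seed = 11))
  b <- suppressWarnings(generateStudyLike(d, seed = 11))
  expect_identical(as.character(a@alignment@sequences),
                   as.character(b@alignment@sequences))
  expect_identical(alleles(a@genotypes), alleles(b@genotypes))
})

test_that("zero selfing yields F_IS near zero; selfing raises it", {
  base <- studyDesign()
  pops <- base$populations
  pops$selfing <- 0
  d0 <- studyDesign(populations = pops)
  fis0 <- vapply(1:8, function(i) {
    ds <- suppressWarnings(generateStudyLike(d0, seed = 100 + i))
    unname(amovaGenotypic(ds@genotypes, nPermutations = 0)@indices["FIS"])
  }, numeric(1))
  expect_lt(abs(mean(fis0)), 0.05)

  pops$selfing <- 0.8
  d1 <- studyDesign(populations = pops)
  fis1 <- vapply(1:8, function(i) {
    ds <- suppressWarnings(generateStudyLike(d1, seed = 100 + i))
    unname(amovaGenotypic(ds@genotypes, nPermutations = 0)@indices["FIS"])
  }, numeric(1))
  expect_gt(mean(fis1), mean(fis0) + 0.2)
})

test_that("high-divergence configuration lands in the strong-structure regime", {
  ds <- suppressWarnings(generateStudyLike(studyDesign(), seed = 21))
  ft <- collapseHaplotypes(ds@alignment, ds@populationOf)
  phi <- amovaHaplotypic(ft, nPermutations = 0)@indices["PhiST"]
  expect_gt(unname(phi), 0.8)
})

test_that("structure statistics respond monotonically to generating parameters", {
  pops <- studyDesign()$populations
  pops$selfing <- 0
  # migration up -> microsatellite F_ST down (two settings x replicates)
  fstAt <- function(m, seeds) mean(vapply(seeds, function(s) {
    d <- studyDesign(populations = pops, m = m)
    ds <- suppressWarnings(generateStudyLike(d, seed = s))
    unname(amovaGenotypic(ds@genotypes, nPermutations = 0)@indices["FST"])
  }, numeric(1)))
  expect_gt(fstAt(1e-5, 300 + 1:6), fstAt(3e-3, 300 + 1:6))

  # theta (deme size) up -> within-population microsatellite diversity up
  heAt <- function(N, seeds) mean(vapply(seeds, function(s) {
    d <- studyDesign(populations = pops, N = N, Nanc = N)
    ds <- suppressWarnings(generateStudyLike(d, seed = s))
    st <- kelpconn:::microsatPopStats(ds@genotypes)
    mean(vapply(st, `[[`, numeric(1), "he"))
  }, numeric(1)))
  expect_gt(heAt(400, 400 + 1:6), heAt(40, 400 + 1:6))
})

test_that("the hypervariable locus carries more alleles than the others", {
  ds <- suppressWarnings(generateStudyLike(studyDesign(), seed = 31))
  A <- alleles(ds@genotypes)$a; B <- alleles(ds@genotypes)$b
  k <- vapply(seq_len(ncol(A)), function(l)
    length(unique(c(A[, l], B[, l]))), numeric(1))
  expect_gt(k[length(k)], max(k[-length(k)]))
})
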