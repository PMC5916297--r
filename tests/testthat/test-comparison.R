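test_that("island-model inversion matches known values and its inverse", {
  expect_equal(islandNmFromFst(0.2), 1.0)
  expect_equal(islandNmFromFst(1.0), 0.0)
  expect_equal(islandNmFromFst(0.268), (1 - 0.268) / (4 * 0.268))
  expect_equal(round(islandNmFromFst(0.268), 3), 0.683)
  expect_error(islandNmFromFst(0), "domain error")
  expect_error(islandNmFromFst(1.2), "domain error")
  # mutual inverses on (0, 1]
  for (f in c(0.01, 0.1, 0.268, 0.7, 1)) {
    expect_equal(fstFromIslandNm(islandNmFromFst(f)), f, tolerance = 1e-12)
    expect_equal(fstFromIslandNm(islandNmFromFst(f, nDemes = 7), nDemes = 7),
                 f, tolerance = 1e-12)
  }
})

test_that("Crow-Aoki half-time evaluates and is monotone in m", {
  expect_equal(crowAokiHalfTime(0, 500), log(2) * 1000, tolerance = 1e-9)
  expect_equal(round(crowAokiHalfTime(0, 500), 2), 693.15)
  expect_equal(round(crowAokiHalfTime(0.01, 1e6), 2), 34.66)
  ms <- c(0.001, 0.01, 0.1, 0.4)
  expect_true(all(diff(crowAokiHalfTime(ms[1], 100) -
                         vapply(ms, crowAokiHalfTime, numeric(1), Ne = 100)) > 0))
  expect_error(crowAokiHalfTime(0.1, 0), "domain error")
})

test_that("connectivity comparison: identical vectors, key mismatch, invariances", {
  fst <- setNames(c(0.2, 0.1, 0.05, 0.3), c("A:B", "A:C", "B:C", "A:D"))
  nm <- vapply(fst, islandNmFromFst, numeric(1))
  im <- data.frame(pair = names(fst), Ma = nm, Mb = nm)
  cmp <- compareConnectivity(fst, im)
  expect_equal(cmp@r, 1)
  expect_equal(cmp@fracBelowUnity, 0)
  expect_equal(cmp@nPairs, 4)

  expect_error(compareConnectivity(fst, im[-1, ]), "key error")

  # Pearson r invariant under affine rescaling of either estimate vector
  im2 <- im; im2$Ma <- 3 * im2$Ma + 1; im2$Mb <- 3 * im2$Mb + 1
  expect_equal(compareConnectivity(fst, im2)@r, cmp@r, tolerance = 1e-12)

  # zero-variance input flags r as undefined
  imc <- im; imc$Ma <- 1; imc$Mb <- 1
  expect_true(is.na(compareConnectivity(fst, imc)@r))
})

test_that("two-tailed p-value follows the t distribution arithmetic", {
  set.seed(2)
  fst <- setNames(runif(21, 0.05, 0.6),
                  paste0("P", 1:21, ":Q", 1:21))
  im <- data.frame(pair = names(fst), Ma = runif(21), Mb = runif(21))
  cmp <- compareConnectivity(fst, im)
  tstat <- cmp@r * sqrt(21 - 2) / sqrt(1 - cmp@r^2)
  expect_equal(cmp@p, 2 * pt(-abs(tstat), 19), tolerance = 1e-12)
  # the published r/p pair is internally consistent with this arithmetic:
  # r = .5129 on 21 pairs gives p = .0174
  expect_equal(2 * pt(-abs(0.5129 * sqrt(19) / sqrt(1 - 0.5129^2)), 19),
               0.017424, tolerance = 1e-3)
})

test_that("published per-pair coalescent estimates load and behave", {
  f <- system.file("extdata", "im_pair_estimates.tsv", package = "kelpconn")
  tab <- read.delim(f)
  expect_equal(nrow(tab), 21)
  # directional means match the connectivity input contract
  m <- (tab$Ma + tab$Mb) / 2
  expect_true(all(m > 0))
  # migration is typically below one effective migrant per generation
  expect_gt(mean(m < 1), 0.7)
})

test_that("island inversion overestimates migration for young splits", {
  # For populations far from migration-drift equilibrium (recent split,
  # near-zero migration), the island-model inversion of F_ST reads drift-
  # driven differentiation as migration and so vastly overstates the true
  # connectivity; comparing against the true simulated migrant numbers
  # puts every pair far below the line of unity.
  cfg <- sampleConfig(nSeq = c(0, 0), nInd = c(15, 15), nMicrosatLoci = 8,
                      muSeq = 0, microsatRateMultipliers = rep(1, 8))
  Mtrue <- 0.02
  young <- vapply(1:5, function(i) {
    p <- imParams(Na = 100, Nb = 100, Nanc = 100, Tsplit = 30,
                  mAB = Mtrue / 200, mBA = Mtrue / 200)
    ds <- simulateIM(p, cfg, seed = 700 + 10 * i)
    unname(amovaGenotypic(ds@genotypes, nPermutations = 0)@indices["FST"])
  }, numeric(1))
  fstY <- setNames(young, paste0("y", 1:5, ":z", 1:5))
  imY <- data.frame(pair = names(fstY), Ma = Mtrue, Mb = Mtrue)
  cmpY <- compareConnectivity(fstY, imY)
  expect_equal(cmpY@fracBelowUnity, 1)
  expect_gt(median(cmpY@pairs$eqNm / cmpY@pairs$noneqM), 10)
})

test_that("equilibrium pairs cluster on the unity line end-to-end", {
  cfg <- sampleConfig(nSeq = c(0, 0), nInd = c(15, 15), nMicrosatLoci = 8,
                      muSeq = 0, microsatRateMultipliers = rep(1, 8))
  priors <- list(N = c(10, 300), Tsplit = c(5, 3000), M = c(0.01, 5))
  eqp <- vapply(1:4, function(i) {
    p <- imParams(Na = 100, Nb = 100, Nanc = 100, Tsplit = 2500,
                  mAB = 0.005, mBA = 0.005)
    ds <- simulateIM(p, cfg, seed = 800 + 10 * i)
    fst <- amovaGenotypic(ds@genotypes, nPermutations = 0)@indices["FST"]
    post <- abcInfer(summarizeDataset(ds), cfg, priors, nSims = 3000,
                     toleranceQuantile = 0.02, seed = 800 + 10 * i + 1)
    c(fst = unname(fst), M = unname(post@pointEstimates["M"]))
  }, numeric(2))
  fstE <- setNames(eqp["fst", ], paste0("y", 1:4, ":z", 1:4))
  imE <- data.frame(pair = names(fstE), Ma = eqp["M", ], Mb = eqp["M", ])
  cmpE <- compareConnectivity(fstE, imE)
  ratio <- median(cmpE@pairs$eqNm / cmpE@pairs$noneqM)
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})
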