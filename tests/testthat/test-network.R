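test_that("single haplotype yields an empty network", {
  ft <- haplotypeFreqTable(matrix(5L, 1, 1, dimnames = list("P", "a")))
  net <- minimumSpanningNetwork(ft, matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$nodes), 1L)
})

test_that("chain topology keeps the long edge as an alternative only when tied", {
  ft <- haplotypeFreqTable(matrix(c(2L, 2L, 2L), 1, 3,
                                  dimnames = list("P", c("A", "B", "C"))))
  net <- minimumSpanningNetwork(ft, chainDistances())
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "B C"))
  # d(A,C)=2 > max weight (1) on tree path, so not an alternative link
  expect_equal(nrow(net$alternativeEdges), 0L)

  # equilateral triangle: one tree edge pair, third edge is an alternative
  D <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(D) <- 0
  net2 <- minimumSpanningNetwork(ft, D)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(nrow(net2$alternativeEdges), 1L)
})

test_that("greedy MST weight equals the exhaustive minimum on random instances", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    D <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    w <- sample(1:5, n * (n - 1) / 2, replace = TRUE)
    D[upper.tri(D)] <- w
    D <- D + t(D)
    ft <- haplotypeFreqTable(matrix(1L, 1, n, dimnames = list("P", LETTERS[1:n])))
    net <- minimumSpanningNetwork(ft, D)
    expect_equal(nrow(net$edges), n - 1L)
    expect_equal(sum(net$edges$steps), bruteMstWeight(D))
  }
})

test_that("tie-break rule makes the network deterministic", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  ft <- haplotypeFreqTable(matrix(1L, 1, 4, dimnames = list("P", letters[1:4])))
  n1 <- minimumSpanningNetwork(ft, D)
  n2 <- minimumSpanningNetwork(ft, D)
  expect_identical(n1$edges, n2$edges)
  # lexicographically first star under (weight, label) ordering
  expect_equal(n1$edges$from, c("a", "a", "a"))
})

test_that("fixture network is the known six-edge tree and exports cleanly", {
  fx <- fixtureHaplotypes()
  net <- minimumSpanningNetwork(fx$freqTable)
  expect_equal(nrow(net$edges), 6L)
  got <- net$edges[order(net$edges$from, net$edges$to), c("from", "to", "steps")]
  want <- fx$edges[order(fx$edges$from, fx$edges$to), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  tsv <- tempfile(fileext = ".tsv"); dot <- tempfile(fileext = ".dot")
  exportNetwork(net, tsv, dot)
  ed <- read.delim(tsv)
  expect_equal(nrow(ed), 6L)
  expect_true(any(grepl("graph msn", readLines(dot))))
})

test_that("MST agrees with an independent implementation when available", {
  skip_if_not_installed("ape")
  set.seed(5)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("h", 1:6)
  D <- pairwiseHamming(seqs)
  ft <- haplotypeFreqTable(matrix(1L, 1, 6, dimnames = list("P", names(seqs))))
  net <- minimumSpanningNetwork(ft, D)
  m <- ape::mst(as.dist(D))
  apeWeight <- sum(D[which(as.matrix(m) == 1)]) / 2
  expect_equal(sum(net$edges$steps), apeWeight)
})
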