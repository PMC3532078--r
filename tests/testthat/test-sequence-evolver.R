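test_that("root sequences follow the root distribution", {
  expect_equal(sampleRootSequence(c(1, 0, 0, 0), 5), "AAAAA")
  expect_error(sampleRootSequence(rep(0.25, 4), 0), "at least 1")
  set.seed(17)
  s <- sampleRootSequence(rep(0.25, 4), 100000)
  se <- sqrt(0.25 * 0.75 / 100000)
  expect_true(all(abs(baseFreqs(s) - 0.25) < 3 * se))
})

test_that("evolveSequence applies the Markov process site by site", {
  expect_equal(evolveSequence("ACGTACGT", diag(4)), "ACGTACGT")
  set.seed(23)
  L <- 200000
  parent <- sampleRootSequence(rep(0.25, 4), L)
  P <- sampleMatrix("jc69", 0.3)
  child <- evolveSequence(parent, P)
  expect_equal(nchar(child), L)
  ## substitution fraction 3b = 3(1 - exp(-0.4))/4
  pSub <- 3 * (1 - exp(-0.4)) / 4
  obs <- mean(strsplit(parent, "")[[1]] != strsplit(child, "")[[1]])
  expect_lt(abs(obs - pSub), 3 * sqrt(pSub * (1 - pSub) / L))
})

test_that("simulateAlignment produces one leaf sequence per taxon and a full record", {
  sim <- simulateAlignment(EXAMPLE_TREE, "k81", L = 2000, seed = 77)
  aln <- alignment(sim)
  expect_equal(length(aln), 5L)
  expect_equal(unname(Biostrings::width(aln)), rep(2000L, 5))
  expect_equal(names(aln), paste0("species", 1:5))
  rec <- simulationRecord(sim)
  expect_equal(length(edgeMatrices(rec)), 6L)
  expect_equal(names(edgeMatrices(rec)),
               c(paste0("species", 1:5), "(species1,species2,species3)"))
  expect_equal(unname(vapply(edgeMatrices(rec), branchLength, numeric(1))),
               EXAMPLE_LENGTHS)
  expect_equal(unname(rootDistribution(rec)), rep(0.25, 4))

  sim2 <- simulateAlignment("(A:0.1,B:0.1);", "jc69", L = 10, seed = 1)
  expect_equal(length(alignment(sim2)), 2L)
  expect_equal(length(edgeMatrices(simulationRecord(sim2))), 2L)
})

test_that("identical seeds reproduce the alignment and parameters bit for bit", {
  s1 <- simulateAlignment(EXAMPLE_TREE, "gmm", L = 500, seed = 99)
  s2 <- simulateAlignment(EXAMPLE_TREE, "gmm", L = 500, seed = 99)
  expect_identical(as.character(alignment(s1)), as.character(alignment(s2)))
  expect_identical(
    lapply(edgeMatrices(simulationRecord(s1)), as.matrix),
    lapply(edgeMatrices(simulationRecord(s2)), as.matrix))
  expect_identical(rootDistribution(simulationRecord(s1)),
                   rootDistribution(simulationRecord(s2)))
  s3 <- simulateAlignment(EXAMPLE_TREE, "gmm", L = 500, seed = 100)
  expect_false(identical(as.character(alignment(s1)),
                         as.character(alignment(s3))))
})

test_that("site patterns fit the exact joint distribution (chi-square, 2-leaf JC69)", {
  sim <- simulateAlignment("(A:0.15,B:0.25);", "jc69", L = 20000, seed = 12)
  rec <- simulationRecord(sim)
  P1 <- as.matrix(edgeMatrices(rec)[["A"]])
  P2 <- as.matrix(edgeMatrices(rec)[["B"]])
  probs <- exactPairJoint(rep(0.25, 4), P1, P2)
  counts <- empiricalJoint(sim, "A", "B")
  expect_equal(sum(counts), 20000)
  gof <- stats::chisq.test(as.vector(counts), p = as.vector(probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("internal node sequences are dropped unless requested", {
  sim <- simulateAlignment(EXAMPLE_TREE, "jc69", L = 50, seed = 5)
  expect_equal(length(sim@internalSequences), 0L)
  simK <- simulateAlignment(EXAMPLE_TREE, "jc69", L = 50, seed = 5,
                            keepInternal = TRUE)
  expect_equal(length(simK@internalSequences), 2L)
  expect_equal(unname(Biostrings::width(simK@internalSequences)), rep(50L, 2))
  ## keeping ancestors does not change the leaf alignment
  expect_identical(as.character(alignment(simK)),
                   as.character(alignment(sim)))
})

test_that("a user-supplied root distribution drives nonstationary composition", {
  pi <- c(0.85, 0.05, 0.05, 0.05)
  sim <- simulateAlignment("(A:0.05,B:0.05);", "gmm", L = 50000, seed = 31,
                           rootDist = pi)
  expect_equal(unname(rootDistribution(simulationRecord(sim))), pi)
  fr <- baseFreqs(alignment(sim)[["A"]])
  expect_gt(fr[1], 0.6)   # composition inherited from the skewed root
})
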