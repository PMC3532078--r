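test_that("branchToDet maps lengths to determinants", {
  expect_equal(branchToDet(0.25), exp(-1), tolerance = 1e-15)
  expect_equal(branchToDet(0.5), exp(-2), tolerance = 1e-15)
  expect_equal(-0.25 * log(branchToDet(0.5)), 0.5, tolerance = 1e-15)
  expect_equal(branchToDet(1e-9), 1, tolerance = 1e-6)   # l -> 0+ gives D -> 1
  expect_error(branchToDet(0), "positive")
  expect_error(branchToDet(-1), "positive")
})

test_that("the JC69 closed form has the stated entries and exact determinant", {
  P <- as.matrix(sampleMatrix("jc69", 0.3))
  expect_equal(P[1, 1], 0.752740, tolerance = 1e-6)
  expect_equal(P[1, 2], 0.082420, tolerance = 1e-6)
  expect_equal(oracleBranchLength(P), 0.3, tolerance = 1e-12)
  ## near-zero length approaches the identity
  P0 <- as.matrix(sampleMatrix("jc69", 1e-8))
  expect_equal(P0, diag(4), tolerance = 1e-7, ignore_attr = TRUE)
  for (l in c(0.05, 0.4, 1.3)) {
    expect_equal(oracleBranchLength(as.matrix(sampleMatrix("jc69", l))), l,
                 tolerance = 1e-12)
  }
})

test_that("isDLC applies the strict column-maximum rule", {
  expect_true(isDLC(diag(4)))
  jc <- matrix(0.2, 4, 4); diag(jc) <- 0.4
  expect_true(isDLC(jc))
  ## K81 with off-diagonal b above the diagonal
  bad <- matrix(c(0.2,0.5,0.2,0.1,
                  0.5,0.2,0.1,0.2,
                  0.2,0.1,0.2,0.5,
                  0.1,0.2,0.5,0.2), 4, 4, byrow = TRUE)
  expect_false(isDLC(bad))
  tie <- diag(4); tie[2, 1] <- 1; tie[2, 2] <- 0   # ties and zeros
  expect_false(isDLC(tie))
})

test_that("makeDlc converts by an allowable even row permutation or reports failure", {
  jc <- matrix(0.2, 4, 4); diag(jc) <- 0.4
  expect_identical(makeDlc(jc, "jc69"), jc)   # already DLC: unchanged

  bad <- matrix(c(0.2,0.5,0.2,0.1,
                  0.5,0.2,0.1,0.2,
                  0.2,0.1,0.2,0.5,
                  0.1,0.2,0.5,0.2), 4, 4, byrow = TRUE)
  fixed <- makeDlc(bad, "k81")
  expect_false(is.null(fixed))
  expect_equal(unname(diag(fixed)), rep(0.5, 4))     # (AC)(GT) swap applied
  expect_true(isDLC(fixed))
  expect_true(patternConforms(fixed, "k81"))
  expect_equal(det(fixed), det(bad), tolerance = 1e-15)  # even permutation

  ## DLC unreachable: column maxima tie across two rows in every column
  stuck <- matrix(c(0.4, 0.4, 0.1, 0.1,
                    0.4, 0.4, 0.1, 0.1,
                    0.1, 0.1, 0.4, 0.4,
                    0.1, 0.1, 0.4, 0.4), 4, 4, byrow = TRUE)
  expect_null(makeDlc(stuck, "gmm"))
})

test_that("sampled matrices meet the determinant, shape and DLC contracts", {
  set.seed(101)
  lengths <- c(0.01, 0.1, 0.5, 1.0)
  for (name in c("jc69", "k80", "k81", "ssm", "gmm")) {
    for (l in lengths) {
      for (rep in 1:20) {
        sm <- sampleMatrix(name, l)
        P <- as.matrix(sm)
        expect_equal(oracleBranchLength(P), l, tolerance = 1e-9,
                     info = sprintf("%s l=%g", name, l))
        expect_true(all(P >= 0))
        expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
        expect_true(patternConforms(P, name))
        expect_true(isDLC(P))
        expect_equal(branchLength(sm), l)
      }
    }
  }
})

test_that("K80/K81 numeric eigenvalues match the sampled parameterisation", {
  set.seed(7)
  for (name in c("k80", "k81")) {
    for (rep in 1:10) {
      P <- as.matrix(sampleMatrix(name, 0.35))
      a <- P[1, 1]; b <- P[1, 2]; cc <- P[1, 3]; d <- P[1, 4]
      expected <- sort(c(1, a + b - cc - d, a - b + cc - d, a - b - cc + d))
      got <- sort(Re(eigen(P, only.values = TRUE)$values))
      expect_equal(got, expected, tolerance = 1e-9)
      expect_equal(prod(expected), branchToDet(0.35), tolerance = 1e-12)
    }
  }
})

test_that("the identity-mixture sampler is non-degenerate and hits the target", {
  set.seed(21)
  seen <- character(0)
  for (rep in 1:50) {
    P <- as.matrix(sampleMatrix("gmm", 0.1))
    expect_equal(oracleBranchLength(P), 0.1, tolerance = 1e-9)
    seen <- c(seen, paste(signif(P, 12), collapse = ","))
  }
  expect_equal(length(unique(seen)), 50L)

  ## SSM draws respect the strand symmetry rows
  for (rep in 1:20) {
    P <- as.matrix(sampleMatrix("ssm", 0.25))
    expect_equal(unname(P[3, ]), unname(rev(P[2, ])), tolerance = 1e-12)
    expect_equal(unname(P[4, ]), unname(rev(P[1, ])), tolerance = 1e-12)
    expect_equal(oracleBranchLength(P), 0.25, tolerance = 1e-9)
  }
})

test_that("extreme branch lengths still satisfy all invariants", {
  set.seed(33)
  P <- sampleMatrix("gmm", 2.9957)  # target determinant ~ 6.1e-6
  expect_equal(oracleBranchLength(as.matrix(P)), 2.9957, tolerance = 1e-9)
  expect_true(isDLC(as.matrix(P)))
  Ps <- sampleMatrix("ssm", 2.0)
  expect_equal(oracleBranchLength(as.matrix(Ps)), 2.0, tolerance = 1e-9)
})

test_that("positive-eigenvalue candidates are DLC at the first check", {
  set.seed(2)
  expect_equal(attr(sampleMatrix("jc69", 0.2), "trials"), 1L)
  ## K80/K81 draws can be rejected for negative entries before the DLC stage,
  ## but a candidate with positive eigenvalues is never rejected for DLC:
  ## the first DLC check performed must pass
  for (name in c("k80", "k81")) {
    checks <- 0L
    countingDLC <- function(P) { checks <<- checks + 1L; isDLC(P) }
    P <- sampleMatrix(name, 0.2, dlcCheck = countingDLC)
    expect_equal(checks, 1L, info = name)
    expect_true(isDLC(as.matrix(P)))
  }
})

test_that("the trial cap aborts with restart advice after exactly the budget", {
  calls <- 0L
  alwaysFail <- function(P) { calls <<- calls + 1L; FALSE }
  set.seed(9)
  expect_error(sampleMatrix("jc69", 0.3, dlcCheck = alwaysFail),
               "re-start")
  expect_equal(calls, 1000L)

  calls <- 0L
  expect_error(
    sampleMatrix("jc69", 0.3, maxTrials = 10, dlcCheck = alwaysFail,
                 edgeLabel = "speciesX"),
    "speciesX")
  expect_equal(calls, 10L)
})
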