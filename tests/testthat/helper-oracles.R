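## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the determinant is a hand-written cofactor
## expansion, and the permutation-group oracle instantiates the model patterns
## (written out again here) with distinct irrational values.

## The worked 5-taxon example tree.
EXAMPLE_TREE <-
  "((species1:0.01,species2:0.2,species3:0.3):0.5,species4:0.4,species5:0.7);"
## branch lengths in canonical edge order: terminal edges (leaf appearance
## order), then the internal root-to-ancestor edge
EXAMPLE_LENGTHS <- c(0.01, 0.2, 0.3, 0.4, 0.7, 0.5)

## 4x4 determinant by cofactor expansion along the first row.
det2x2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
det3x3 <- function(m) {
  m[1, 1] * det2x2(m[2:3, 2:3, drop = FALSE]) -
  m[1, 2] * det2x2(m[2:3, c(1, 3), drop = FALSE]) +
  m[1, 3] * det2x2(m[2:3, 1:2, drop = FALSE])
}
det4x4 <- function(m) {
  s <- 0
  for (j in 1:4) {
    s <- s + (-1)^(1 + j) * m[1, j] * det3x3(m[-1, -j, drop = FALSE])
  }
  s
}

## Branch length via the cofactor determinant.
oracleBranchLength <- function(P) -0.25 * log(det4x4(as.matrix(P)))

## Model patterns, restated independently of the package source.
ORACLE_PATTERNS <- list(
  JC69 = matrix(c("a","b","b","b","b","a","b","b",
                  "b","b","a","b","b","b","b","a"), 4, 4, byrow = TRUE),
  K80  = matrix(c("a","b","c","b","b","a","b","c",
                  "c","b","a","b","b","c","b","a"), 4, 4, byrow = TRUE),
  K81  = matrix(c("a","b","c","d","b","a","d","c",
                  "c","d","a","b","d","c","b","a"), 4, 4, byrow = TRUE),
  SSM  = matrix(c("a","b","c","d","e","f","g","h",
                  "h","g","f","e","d","c","b","a"), 4, 4, byrow = TRUE),
  GMM  = matrix(letters[1:16], 4, 4, byrow = TRUE)
)

## All 24 permutations of 1:4.
allPerms4 <- local({
  out <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j)))
    out[[length(out) + 1L]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
  out
})

permKey <- function(p) paste(p, collapse = "")

## Pattern-group oracle: instantiate the labels with distinct irrational
## values (square roots of primes), so two cells are numerically equal iff
## they carry the same label. A row permutation preserves the pattern up to
## relabelling iff the equality classes of the permuted matrix coincide with
## the pattern's label classes.
oraclePermGroup <- function(pattern) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53)
  vals <- sqrt(primes)[match(as.vector(pattern), letters)]
  M <- matrix(vals, 4, 4)
  classesOf <- function(m) {
    key <- match(as.vector(m), unique(as.vector(m)))
    split(seq_len(16), key)
  }
  ref <- classesOf(M)
  canon <- function(cl) sort(vapply(cl, function(ix)
    paste(sort(ix), collapse = ","), character(1)))
  Filter(function(sigma) {
    identical(canon(classesOf(M[sigma, , drop = FALSE])), canon(ref))
  }, allPerms4)
}

## Exact joint distribution of a pair of leaves hanging off a common root.
exactPairJoint <- function(pi, P1, P2) {
  t(as.matrix(P1)) %*% diag(pi) %*% as.matrix(P2)
}

## Base composition of a character DNA sequence.
baseFreqs <- function(s) {
  x <- strsplit(as.character(s), "", fixed = TRUE)[[1]]
  counts <- table(factor(x, levels = c("A", "C", "G", "T")))
  as.numeric(counts) / length(x)
}

writeTempTree <- function(text = EXAMPLE_TREE) {
  f <- tempfile(fileext = ".txt")
  writeLines(text, f)
  f
}
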