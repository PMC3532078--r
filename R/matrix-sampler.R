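## Samplers for row-stochastic substitution matrices with a prescribed
## log-determinant branch length l = -1/4 log det(P), converted to DLC
## (diagonal largest in column) form. JC69 has a closed form; K80/K81 are
## sampled through their eigenvalue parameterisation; SSM/GMM by mixing a
## random matrix of the right shape with the identity until the determinant
## constraint is hit (the shape classes are convex and contain the identity).

#' Target determinant for a branch length
#'
#' Under the log-determinant branch-length convention l = -1/4 log det(P), an
#' edge of length `l` requires det(P) = exp(-4 l), in (0, 1).
#'
#' @param l branch length, expected substitutions per site; must be > 0
#' @return the target determinant exp(-4 l)
#' @examples
#' branchToDet(0.25)  # exp(-1)
#' @export
branchToDet <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0)
    stop("branch length must be a single finite positive number")
  exp(-4 * l)
}

#' Is a matrix DLC (diagonal largest in column)?
#'
#' TRUE iff for every column the diagonal entry is strictly larger than every
#' off-diagonal entry of that column. Ties fail: identifiability of the
#' generating parameters requires the strict form.
#'
#' @param P a 4x4 numeric matrix
#' @return logical
#' @examples
#' isDLC(diag(4))
#' @export
isDLC <- function(P) {
  for (j in 1:4) if (any(P[-j, j] >= P[j, j])) return(FALSE)
  TRUE
}

## --- model-specific draws -------------------------------------------------
## Each returns a plain 4x4 matrix satisfying the determinant constraint, or
## NULL for a rejected draw (counted as a failed trial by sampleMatrix).

## K81 matrices are symmetric with eigenvalues 1, x = a+b-c-d, y = a-b+c-d,
## z = a-b-c+d; det = x y z. Entries recovered by the inverse Hadamard-type
## relations below.
.buildK81 <- function(x, y, z) {
  a <- (1 + x + y + z) / 4
  b <- (1 + x - y - z) / 4
  cc <- (1 - x + y - z) / 4
  d <- (1 - x - y + z) / 4
  if (min(a, b, cc, d) < 0) return(NULL)
  matrix(c(a,  b,  cc, d,
           b,  a,  d,  cc,
           cc, d,  a,  b,
           d,  cc, b,  a),
         4L, 4L, byrow = TRUE, dimnames = list(.NUC, .NUC))
}

.drawJC69 <- function(l) {
  e <- exp(-4 * l / 3)
  .buildK81(e, e, e)
}

## x, y, z sampled positive so the diagonal a = (1+x+y+z)/4 strictly dominates
## and the draw is DLC by construction; z = D/(x y) makes det exact.
.drawK81 <- function(D) {
  x <- stats::runif(1, D, 1)
  y <- stats::runif(1, D / x, 1)
  z <- D / (x * y)
  .buildK81(x, y, z)
}

## K80 = K81 with b = d: eigenvalues (x, x, y), det = x^2 y.
.drawK80 <- function(D) {
  x <- stats::runif(1, sqrt(D), 1)
  y <- D / x^2
  .buildK81(x, y, x)
}

.drawDirichletRows <- function(n) {
  g <- matrix(stats::rexp(4L * n), nrow = n)
  g / rowSums(g)
}

.drawShapeSSM <- function() {
  rows <- .drawDirichletRows(2L)
  rbind(rows, rows[2L, 4:1], rows[1L, 4:1])
}

.drawShapeGMM <- function() {
  .drawDirichletRows(4L)
}

## Coefficients of the quartic f(s) = det((1-s) I + s M) = det(I + s (M - I)):
## f(s) = 1 + e1 s + e2 s^2 + e3 s^3 + e4 s^4 with e_k the sum of the k x k
## principal minors of B = M - I.
.mixturePoly <- function(M) {
  B <- M - diag(4)
  e1 <- sum(diag(B))
  idx2 <- utils::combn(4, 2)
  e2 <- sum(apply(idx2, 2, function(ii) det(B[ii, ii])))
  idx3 <- utils::combn(4, 3)
  e3 <- sum(apply(idx3, 2, function(ii) det(B[ii, ii])))
  e4 <- det(B)
  c(1, e1, e2, e3, e4)
}

.evalPoly <- function(coef, s) {
  ((coef[5] * s + coef[4]) * s + coef[3]) * s^2 + coef[2] * s + coef[1]
}

## One identity-mixture draw for SSM/GMM: draw M of the model's shape, reject
## if det(M) >= D, otherwise return P(s*) = (1-s*) I + s* M at the first
## crossing of det P(s) = D. The crossing is bracketed on a grid of step
## 1/1000 (f need not be monotone; the first crossing favours more diagonally
## dominant, DLC-friendly matrices) and refined by bisection until the branch
## length -1/4 log f(s) matches l to 1e-12.
.drawMixture <- function(model, l, D) {
  M <- if (model == "SSM") .drawShapeSSM() else .drawShapeGMM()
  coef <- .mixturePoly(M)
  if (.evalPoly(coef, 1) >= D) return(NULL)    # det(M) >= D: reject
  grid <- seq_len(1000L) / 1000
  fs <- .evalPoly(coef, grid)
  k <- which(fs <= D)[1L]                      # exists: f(1) = det(M) < D
  lo <- (k - 1L) / 1000
  hi <- grid[k]
  for (iter in 1:200) {
    fhi <- .evalPoly(coef, hi)
    if (fhi > 0 && abs(-0.25 * log(fhi) - l) <= 1e-12) break
    mid <- (lo + hi) / 2
    if (.evalPoly(coef, mid) > D) lo <- mid else hi <- mid
  }
  P <- (1 - hi) * diag(4) + hi * M
  dimnames(P) <- list(.NUC, .NUC)
  P
}

#' Convert a matrix to DLC form by an allowable row permutation
#'
#' If `P` is already DLC it is returned unchanged; otherwise each
#' pattern-preserving row permutation of the model is tried and the first
#' permuted matrix that is DLC is returned. Only even permutations are used:
#' an odd row permutation negates the determinant and would break the
#' log-determinant branch length of the matrix (this only restricts the
#' general Markov model, whose full permutation group is all of S4; the
#' JC69/K80/K81/SSM groups contain even permutations only).
#'
#' @param P a 4x4 numeric matrix conforming to the model's pattern
#' @param model a [ModelSpec] or model name
#' @param dlcCheck predicate used to test the DLC property (exposed for
#'   testing; defaults to [isDLC()])
#' @return the DLC matrix, or `NULL` if no allowable permutation yields one
#'   (a failure signal, so callers can resample)
#' @export
makeDlc <- function(P, model, dlcCheck = isDLC) {
  if (is(P, "SubstitutionMatrix")) P <- P@entries
  if (dlcCheck(P)) return(P)
  model <- getModel(model)
  for (sigma in model@permGroup) {
    if (identical(sigma, 1:4) || .permSign(sigma) < 0L) next
    Q <- P[sigma, , drop = FALSE]
    rownames(Q) <- .NUC
    if (dlcCheck(Q)) return(Q)
  }
  NULL
}

#' Sample a substitution matrix with a prescribed branch length
#'
#' Draws a random row-stochastic matrix of the model's shape whose
#' log-determinant branch length -1/4 log det(P) equals `l` exactly, converted
#' to DLC form. JC69 is the deterministic closed form (diagonal (1+3e)/4,
#' off-diagonal (1-e)/4 with e = exp(-4l/3)); K80 and K81 are drawn through
#' their eigenvalue parameterisation with positive eigenvalues (DLC by
#' construction); SSM and GMM are drawn by mixing a random shape-conformant
#' matrix with the identity to the determinant target (see [makeDlc()] for
#' the DLC conversion). Draws rejected for negative entries, a too-large
#' determinant or DLC failure are retried, up to `maxTrials` attempts in
#' total, after which the simulation aborts with a restart error.
#'
#' Uses R's global RNG; call `set.seed()` for reproducibility. The number of
#' trials used is attached as `attr(result, "trials")`.
#'
#' @param model a [ModelSpec] or model name
#' @param l branch length, expected substitutions per site; must be > 0
#' @param maxTrials trial budget before aborting (default 1000)
#' @param dlcCheck DLC predicate, exposed for testing (default [isDLC()])
#' @param edgeLabel optional label naming the edge in error messages
#' @return a [SubstitutionMatrix]
#' @examples
#' set.seed(1)
#' P <- sampleMatrix("k81", 0.2)
#' -0.25 * log(det(as.matrix(P)))  # 0.2
#' @export
sampleMatrix <- function(model, l, maxTrials = 1000L, dlcCheck = isDLC,
                         edgeLabel = NULL) {
  model <- getModel(model)
  if (!is.numeric(maxTrials) || maxTrials < 1L)
    stop("maxTrials must be at least 1")
  D <- branchToDet(l)
  for (trial in seq_len(maxTrials)) {
    P <- switch(model@name,
      JC69 = .drawJC69(l),
      K80  = .drawK80(D),
      K81  = .drawK81(D),
      SSM  = .drawMixture("SSM", l, D),
      GMM  = .drawMixture("GMM", l, D))
    if (is.null(P)) next
    Q <- makeDlc(P, model, dlcCheck = dlcCheck)
    if (is.null(Q)) next
    out <- new("SubstitutionMatrix",
               entries = Q, modelName = model@name, branchLength = l)
    attr(out, "trials") <- trial
    return(out)
  }
  stop(sprintf(paste0(
    "no DLC matrix of model %s found for branch length %g%s after %d trials; ",
    "the simulation requires a re-start (try a different seed)"),
    model@name, l,
    if (is.null(edgeLabel)) "" else sprintf(" (edge to %s)", edgeLabel),
    maxTrials))
}

## Identity matrix as a SubstitutionMatrix (zero-length edges, when allowed).
.identityMatrix <- function(model) {
  model <- getModel(model)
  P <- diag(4)
  dimnames(P) <- list(.NUC, .NUC)
  new("SubstitutionMatrix", entries = P, modelName = model@name,
      branchLength = 0)
}

#' @describeIn SubstitutionMatrix-class the 4x4 numeric entries
#' @param x a SubstitutionMatrix
#' @param ... unused
#' @export
setMethod("as.matrix", "SubstitutionMatrix", function(x, ...) x@entries)

#' @describeIn SubstitutionMatrix-class branch length of the matrix
#' @export
setMethod("branchLength", "SubstitutionMatrix", function(x) x@branchLength)

#' @describeIn SubstitutionMatrix-class name of the model class
#' @export
setMethod("modelName", "SubstitutionMatrix", function(x) x@modelName)

#' @describeIn SubstitutionMatrix-class display entries and branch length
#' @param object a SubstitutionMatrix
#' @export
setMethod("show", "SubstitutionMatrix", function(object) {
  cat(sprintf("%s substitution matrix, branch length %g (det = %g)\n",
              object@modelName, object@branchLength, det(object@entries)))
  print(round(object@entries, 6))
})
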