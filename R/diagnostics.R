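## Diagnostics used to validate simulated data: empirical pairwise joint
## distributions and the log-det (paralinear) distance, which recovers path
## lengths from the data whenever the marginal base compositions are uniform
## (JC69/K80/K81 with their uniform stationary root). For nonstationary
## models (SSM/GMM) the paralinear distance remains well defined but is not
## in general the sum of the per-edge log-det branch lengths.

#' Empirical joint base-pair counts for a leaf pair
#'
#' Counts, over the alignment columns, how often leaf `u` shows state i while
#' leaf `v` shows state j, giving the 4x4 joint count matrix (rows = states of
#' `u`, columns = states of `v`, order A,C,G,T). Entries sum to the alignment
#' length.
#'
#' @param aln a `DNAStringSet`, [SimulationResult] or named character vector
#' @param u,v two distinct leaf names present in the alignment
#' @return 4x4 integer matrix of counts
#' @export
empiricalJoint <- function(aln, u, v) {
  if (is(aln, "SimulationResult")) aln <- alignment(aln)
  if (!is(aln, "XStringSet")) aln <- Biostrings::DNAStringSet(aln)
  if (!u %in% names(aln)) stop(sprintf("unknown leaf '%s'", u))
  if (!v %in% names(aln)) stop(sprintf("unknown leaf '%s'", v))
  if (identical(u, v)) stop("u and v must be distinct leaves")
  x <- .stringToCodes(aln[[u]])
  y <- .stringToCodes(aln[[v]])
  counts <- table(factor(x, levels = 1:4), factor(y, levels = 1:4))
  counts <- matrix(as.integer(counts), 4L, 4L, dimnames = list(.NUC, .NUC))
  counts
}

#' Paralinear (log-det) distance from a joint distribution
#'
#' For the relative-frequency matrix F = J / sum(J) with row marginals f and
#' column marginals g, the paralinear distance is
#' d = -1/4 \[ log |det F| - 1/2 log (prod f_i * prod g_j) \].
#' It is additive along tree paths and, when all marginals are uniform (the
#' stationary JC69/K80/K81 case), equals the sum of the log-det branch
#' lengths on the path between the two leaves. The absolute value guards
#' against tiny negative determinants arising from sampling noise at short
#' alignments.
#'
#' @param J 4x4 matrix of joint counts or probabilities (see
#'   [empiricalJoint()])
#' @return the distance, expected substitutions per site
#' @export
paralinearDistance <- function(J) {
  J <- as.matrix(J)
  stopifnot(identical(dim(J), c(4L, 4L)), all(J >= 0))
  F <- J / sum(J)
  f <- rowSums(F)
  g <- colSums(F)
  if (any(f <= 0) || any(g <= 0))
    stop("zero marginal: distance undefined (try a longer alignment)")
  dF <- det(F)
  if (dF == 0)
    stop("singular joint distribution: distance undefined (try a longer alignment)")
  -0.25 * (log(abs(dF)) - 0.5 * (sum(log(f)) + sum(log(g))))
}

#' Log-determinant branch length of a substitution matrix
#'
#' The branch length attributed to a transition matrix under the
#' log-determinant convention, -1/4 log det(P); the quantity the matrix
#' samplers hold equal to the input edge length.
#'
#' @param P a 4x4 matrix or [SubstitutionMatrix] with positive determinant
#' @return the branch length, expected substitutions per site
#' @examples
#' logdetBranchLength(diag(4))  # 0
#' @export
logdetBranchLength <- function(P) {
  if (is(P, "SubstitutionMatrix")) P <- P@entries
  d <- det(P)
  if (d <= 0) stop("determinant must be positive")
  -0.25 * log(d)
}
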