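#' @import methods
NULL

## Nucleotide alphabet order used throughout: A, C, G, T.
.NUC <- c("A", "C", "G", "T")

## Numerical tolerances (package-wide constants).
## .TOL_ROWSUM: row-stochasticity; .TOL_PATTERN: equal-label cells of a model
## pattern; .TOL_LENGTH: agreement of -1/4 log det(P) with the requested branch
## length.
.TOL_ROWSUM  <- 1e-12
.TOL_PATTERN <- 1e-12
.TOL_LENGTH  <- 1e-9

#' ModelSpec: a discrete-time substitution model class
#'
#' A symbolic description of one of the five supported model classes: the 4x4
#' pattern of parameter labels (rows = parent state, columns = child state, in
#' A,C,G,T order), the number of free parameters per matrix after the row-sum
#' constraint, the set of row permutations that preserve the pattern up to a
#' relabelling of parameters, and the family of admissible root distributions.
#'
#' @slot name model name, one of "JC69", "K80", "K81", "SSM", "GMM"
#' @slot pattern 4x4 character matrix of parameter labels
#' @slot nFreeParams integer, free parameters per substitution matrix
#' @slot permGroup list of integer permutations of 1:4 (row permutations
#'   sigma such that P[sigma, ] has the same pattern for every P of the model)
#' @slot rootFamily character, one of "uniform" (JC69/K80/K81),
#'   "strand-symmetric" (SSM) or "simplex" (GMM)
#' @export
setClass("ModelSpec",
  representation(
    name        = "character",
    pattern     = "matrix",
    nFreeParams = "integer",
    permGroup   = "list",
    rootFamily  = "character"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!identical(dim(object@pattern), c(4L, 4L)))
    msg <- c(msg, "pattern must be a 4x4 matrix")
  if (!is.character(object@pattern))
    msg <- c(msg, "pattern must hold character labels")
  if (length(object@permGroup) < 1L ||
      !all(vapply(object@permGroup, function(p)
        identical(sort(p), 1:4), logical(1))))
    msg <- c(msg, "permGroup must be a list of permutations of 1:4")
  if (!object@rootFamily %in% c("uniform", "strand-symmetric", "simplex"))
    msg <- c(msg, "unknown root distribution family")
  if (length(msg)) msg else TRUE
})

#' SubstitutionMatrix: an edge transition matrix with a prescribed branch length
#'
#' A 4x4 row-stochastic matrix P (rows = parent state, columns = child state,
#' A,C,G,T order) that conforms to its model's symbolic pattern, satisfies the
#' log-determinant branch-length constraint -1/4 log det(P) = branchLength, and
#' is DLC (diagonal largest in column: the diagonal entry is strictly the
#' largest entry of every column), which makes the generating parameters
#' identifiable from the joint leaf distribution.
#'
#' @slot entries 4x4 numeric matrix of conditional probabilities
#' @slot modelName name of the model class the matrix belongs to
#' @slot branchLength branch length in expected substitutions per site
#' @export
setClass("SubstitutionMatrix",
  representation(
    entries      = "matrix",
    modelName    = "character",
    branchLength = "numeric"
  )
)

setValidity("SubstitutionMatrix", function(object) {
  P <- object@entries
  msg <- character()
  if (!identical(dim(P), c(4L, 4L)) || !is.numeric(P))
    return("entries must be a numeric 4x4 matrix")
  if (any(P < 0))
    msg <- c(msg, "negative entries")
  if (any(abs(rowSums(P) - 1) > .TOL_ROWSUM))
    msg <- c(msg, "rows must sum to 1")
  model <- tryCatch(getModel(object@modelName), error = function(e) NULL)
  if (is.null(model)) {
    msg <- c(msg, sprintf("unknown model '%s'", object@modelName))
  } else if (!patternConforms(P, model)) {
    msg <- c(msg, sprintf("entries do not match the %s pattern", model@name))
  }
  l <- object@branchLength
  if (length(l) != 1L || !is.finite(l) || l < 0) {
    msg <- c(msg, "branchLength must be a single finite nonnegative number")
  } else {
    d <- det(P)
    if (d <= 0) {
      msg <- c(msg, "determinant must be positive")
    } else if (abs(-0.25 * log(d) - l) > .TOL_LENGTH) {
      msg <- c(msg, sprintf(
        "-1/4 log det = %.12g does not match branchLength %.12g",
        -0.25 * log(d), l))
    }
  }
  if (!isDLC(P))
    msg <- c(msg, "matrix is not DLC (diagonal largest in column)")
  if (length(msg)) msg else TRUE
})

#' SimulationRecord: every parameter used in one simulation
#'
#' Holds the model name, the input Newick text, the root distribution, the
#' seed (NA if none was supplied) and one SubstitutionMatrix per edge in the
#' canonical output order (terminal edges first, in leaf appearance order,
#' then internal edges top-down from the root; see [edgesInOutputOrder()]).
#'
#' @slot modelName model class used
#' @slot treeText the input Newick string
#' @slot rootDistribution numeric 4-vector over (A,C,G,T)
#' @slot edgeLabels character labels of the edges, canonical order
#' @slot edgeLengths numeric branch lengths, canonical order
#' @slot edgeMatrices list of SubstitutionMatrix, canonical order
#' @slot seed integer seed, NA when the RNG state was not seeded explicitly
#' @export
setClass("SimulationRecord",
  representation(
    modelName        = "character",
    treeText         = "character",
    rootDistribution = "numeric",
    edgeLabels       = "character",
    edgeLengths      = "numeric",
    edgeMatrices     = "list",
    seed             = "integer"
  )
)

setValidity("SimulationRecord", function(object) {
  msg <- character()
  n <- length(object@edgeMatrices)
  if (length(object@edgeLabels) != n || length(object@edgeLengths) != n)
    msg <- c(msg, "edgeLabels, edgeLengths and edgeMatrices must align")
  if (!all(vapply(object@edgeMatrices, is, logical(1), "SubstitutionMatrix")))
    msg <- c(msg, "edgeMatrices must hold SubstitutionMatrix objects")
  pi <- object@rootDistribution
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    msg <- c(msg, "rootDistribution must be a probability 4-vector")
  if (length(msg)) msg else TRUE
})

#' SimulationResult: alignment plus the parameters that generated it
#'
#' @slot alignment a [Biostrings::DNAStringSet] of the leaf sequences, in leaf
#'   appearance order
#' @slot record the [SimulationRecord] of parameters used
#' @slot internalSequences DNAStringSet of ancestral (internal node)
#'   sequences; empty unless the simulation was run with `keepInternal = TRUE`
#' @export
setClass("SimulationResult",
  representation(
    alignment         = "DNAStringSet",
    record            = "SimulationRecord",
    internalSequences = "DNAStringSet"
  )
)
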