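## The five discrete-time model classes. Pattern rows/columns are indexed by
## the nucleotides in alphabet order (A, C, G, T); equal labels mark entries
## constrained to be equal. Parameter c sits on the transition cells
## (A<->G, C<->T) for K80/K81.

.modelPattern <- function(labels) {
  matrix(labels, 4L, 4L, byrow = TRUE, dimnames = list(.NUC, .NUC))
}

.MODEL_PATTERNS <- list(
  JC69 = .modelPattern(c("a","b","b","b",
                         "b","a","b","b",
                         "b","b","a","b",
                         "b","b","b","a")),
  K80  = .modelPattern(c("a","b","c","b",
                         "b","a","b","c",
                         "c","b","a","b",
                         "b","c","b","a")),
  K81  = .modelPattern(c("a","b","c","d",
                         "b","a","d","c",
                         "c","d","a","b",
                         "d","c","b","a")),
  SSM  = .modelPattern(c("a","b","c","d",
                         "e","f","g","h",
                         "h","g","f","e",
                         "d","c","b","a")),
  GMM  = .modelPattern(letters[1:16])
)

.MODEL_FREE_PARAMS <- c(JC69 = 1L, K80 = 2L, K81 = 3L, SSM = 6L, GMM = 12L)

.MODEL_ROOT_FAMILY <- c(JC69 = "uniform", K80 = "uniform", K81 = "uniform",
                        SSM = "strand-symmetric", GMM = "simplex")

## All 24 permutations of 1:4, generated once at load time.
.ALL_PERMS_4 <- local({
  out <- list()
  for (i in 1:4) for (j in setdiff(1:4, i))
    for (k in setdiff(1:4, c(i, j))) {
      out[[length(out) + 1L]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
    }
  out
})

## Sign of a permutation via inversion count.
.permSign <- function(p) {
  inv <- 0L
  for (i in seq_along(p)) inv <- inv + sum(p[seq_len(i - 1L)] > p[i])
  if (inv %% 2L == 0L) 1L else -1L
}

## TRUE iff the row permutation sigma maps the pattern to itself up to a
## bijective relabelling of the parameter labels: the cell-wise map
## pattern[i,j] -> pattern[sigma[i], j] must be a well-defined injection.
.patternPreserved <- function(pattern, sigma) {
  orig <- as.vector(pattern)
  perm <- as.vector(pattern[sigma, , drop = FALSE])
  images <- split(perm, orig)
  if (any(vapply(images, function(v) length(unique(v)), integer(1)) != 1L))
    return(FALSE)
  img <- vapply(images, `[`, character(1), 1L)
  length(unique(img)) == length(img)
}

## Cache of constructed ModelSpec objects (the permutation groups are computed
## once by brute force over S4).
.modelCache <- new.env(parent = emptyenv())

#' Retrieve a model specification
#'
#' Returns the [ModelSpec] for one of the five supported discrete-time Markov
#' model classes: the Jukes-Cantor (JC69), Kimura 2-parameter (K80), Kimura
#' 3-parameter (K81), strand symmetric (SSM) and general Markov (GMM) models.
#' The pattern-preserving row-permutation group is computed symbolically by
#' checking all 24 permutations of the rows against the model's label pattern.
#'
#' @param name model name, case-insensitive: "jc69", "k80", "k81", "ssm" or
#'   "gmm". A ModelSpec is returned unchanged.
#' @return a [ModelSpec]
#' @examples
#' getModel("k81")
#' @export
getModel <- function(name) {
  if (is(name, "ModelSpec")) return(name)
  if (!is.character(name) || length(name) != 1L)
    stop("model must be a single name or a ModelSpec")
  key <- toupper(name)
  if (!key %in% names(.MODEL_PATTERNS))
    stop(sprintf("unknown model '%s'; valid models are: %s",
                 name, paste(tolower(names(.MODEL_PATTERNS)), collapse = ", ")))
  if (!is.null(.modelCache[[key]])) return(.modelCache[[key]])
  pattern <- .MODEL_PATTERNS[[key]]
  group <- Filter(function(p) .patternPreserved(pattern, p), .ALL_PERMS_4)
  spec <- new("ModelSpec",
              name        = key,
              pattern     = pattern,
              nFreeParams = .MODEL_FREE_PARAMS[[key]],
              permGroup   = group,
              rootFamily  = .MODEL_ROOT_FAMILY[[key]])
  .modelCache[[key]] <- spec
  spec
}

#' Row permutations preserving a model's matrix pattern
#'
#' The set of permutations sigma of the rows (states A,C,G,T) such that for
#' every matrix P of the model's shape, P with rows permuted by sigma still
#' has the model's shape, up to a relabelling of the parameters. These are the
#' permutations available to convert a sampled matrix to DLC form without
#' leaving the model class.
#'
#' @param model a [ModelSpec] or model name
#' @return a list of integer permutations of 1:4
#' @examples
#' length(allowablePermutations("gmm"))  # 24: the pattern is unconstrained
#' allowablePermutations("k81")          # the Klein four-group
#' @export
allowablePermutations <- function(model) {
  getModel(model)@permGroup
}

#' Does a numeric matrix conform to a model's symbolic pattern?
#'
#' Cells carrying the same parameter label must be numerically equal (within
#' `tol`); distinct labels are unconstrained.
#'
#' @param P numeric 4x4 matrix
#' @param model a [ModelSpec] or model name
#' @param tol equality tolerance for equal-label cells
#' @return logical
#' @export
patternConforms <- function(P, model, tol = .TOL_PATTERN) {
  pattern <- getModel(model)@pattern
  labels <- as.vector(pattern)
  vals <- as.vector(P)
  for (grp in split(vals, labels)) {
    if (max(grp) - min(grp) > tol) return(FALSE)
  }
  TRUE
}

#' Draw a root distribution from a model's family
#'
#' JC69, K80 and K81 matrices are doubly stochastic, so their root
#' distribution is the uniform (1/4, 1/4, 1/4, 1/4), which they hold
#' stationary. The strand symmetric model constrains pi_A = pi_T and
#' pi_C = pi_G; a draw sets pi_A = p with p uniform on (0, 1/2). The general
#' Markov model places no constraint; a draw is flat Dirichlet on the
#' 3-simplex. Uses R's global RNG; call `set.seed()` for reproducibility.
#'
#' @param model a [ModelSpec] or model name
#' @return numeric 4-vector of probabilities over (A, C, G, T)
#' @export
sampleRootDistribution <- function(model) {
  model <- getModel(model)
  pi <- switch(model@rootFamily,
    "uniform" = rep(0.25, 4),
    "strand-symmetric" = {
      p <- stats::runif(1, 0, 0.5)
      c(p, 0.5 - p, 0.5 - p, p)
    },
    "simplex" = {
      g <- stats::rexp(4)
      g / sum(g)
    })
  names(pi) <- .NUC
  pi
}

#' @describeIn ModelSpec-class display the pattern and permutation group
#' @param object a ModelSpec
#' @export
setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("%s discrete-time substitution model (%d free parameter%s)\n",
              object@name, object@nFreeParams,
              if (object@nFreeParams == 1L) "" else "s"))
  cat("pattern (rows = parent, cols = child, A C G T):\n")
  print(object@pattern, quote = FALSE)
  cat(sprintf("pattern-preserving row permutations: %d\n",
              length(object@permGroup)))
  cat(sprintf("root distribution family: %s\n", object@rootFamily))
})
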