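## Site-independent evolution of sequences down the tree. Sequences are held
## internally as integer codes 1..4 over (A, C, G, T); sites are i.i.d., with
## no rate variation across sites and no indels, matching the model family:
## the only parameters are the root distribution and one substitution matrix
## per edge.

.codesToString <- function(codes) paste(.NUC[codes], collapse = "")

.stringToCodes <- function(s) {
  codes <- match(strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1]],
                 .NUC)
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T}")
  codes
}

.sampleRootCodes <- function(pi, L) {
  sample.int(4L, size = L, replace = TRUE, prob = pi)
}

.evolveCodes <- function(codes, P) {
  out <- integer(length(codes))
  for (s in 1:4) {
    idx <- which(codes == s)
    if (length(idx))
      out[idx] <- sample.int(4L, size = length(idx), replace = TRUE,
                             prob = P[s, ])
  }
  out
}

#' Draw a root sequence
#'
#' `L` bases drawn i.i.d. from the root distribution `pi` over (A, C, G, T).
#' Uses R's global RNG.
#'
#' @param pi probability 4-vector over (A, C, G, T)
#' @param L number of sites, at least 1
#' @return a character string of length `L` over ACGT
#' @export
sampleRootSequence <- function(pi, L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("alignment length L must be at least 1")
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be a probability 4-vector")
  .codesToString(.sampleRootCodes(pi, as.integer(L)))
}

#' Evolve a sequence across one edge
#'
#' Each site's child state is drawn independently from the row of `P` indexed
#' by the parent state; the Markov process acts site by site, so the output
#' has the same length as the input.
#'
#' @param parentSeq a character string over ACGT (or a `DNAString`)
#' @param P a [SubstitutionMatrix] or a plain row-stochastic 4x4 matrix in
#'   (A,C,G,T) order
#' @return the child sequence, a character string of the same length
#' @export
evolveSequence <- function(parentSeq, P) {
  if (is(P, "SubstitutionMatrix")) P <- P@entries
  .codesToString(.evolveCodes(.stringToCodes(parentSeq), P))
}

#' Simulate an alignment on a tree
#'
#' Runs the full simulation: one substitution matrix per edge is drawn with
#' [sampleMatrix()] (in the canonical output order of
#' [edgesInOutputOrder()]), a root sequence of length `L` is drawn from the
#' model's root distribution, and the sequence is propagated down the tree in
#' pre-order (children in Newick order), each edge applying its matrix site
#' by site. Only the leaf sequences enter the alignment; ancestral sequences
#' are kept only when `keepInternal = TRUE`.
#'
#' With a fixed `seed` the run is fully reproducible: the RNG consumption
#' order (matrices, then root sequence, then edges in pre-order) is part of
#' the contract.
#'
#' @param tree an `ape` `phylo` tree from [parseNewick()]/[readNewickTree()],
#'   or a Newick string
#' @param model a [ModelSpec] or model name (jc69, k80, k81, ssm, gmm)
#' @param L alignment length in sites, at least 1
#' @param seed optional integer seed; recorded in the [SimulationRecord]
#' @param rootDist optional root distribution overriding the model's draw
#'   (probability 4-vector over A,C,G,T); useful for constructing specific
#'   nonstationary scenarios
#' @param maxTrials per-edge trial budget for [sampleMatrix()]
#' @param keepInternal retain ancestral node sequences in the result
#' @return a [SimulationResult] holding the leaf alignment (a
#'   `DNAStringSet`) and the [SimulationRecord] of all parameters used
#' @examples
#' tr <- parseNewick("(A:0.1,B:0.3);")
#' sim <- simulateAlignment(tr, "jc69", L = 100, seed = 7)
#' alignment(sim)
#' @export
simulateAlignment <- function(tree, model, L, seed = NULL, rootDist = NULL,
                              maxTrials = 1000L, keepInternal = FALSE) {
  if (is.character(tree)) tree <- parseNewick(tree)
  stopifnot(inherits(tree, "phylo"))
  model <- getModel(model)
  if (!is.numeric(L) || length(L) != 1L || L < 1)
    stop("alignment length L must be at least 1")
  L <- as.integer(L)
  if (!is.null(seed)) set.seed(seed)

  pi <- if (is.null(rootDist)) sampleRootDistribution(model) else rootDist
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("rootDist must be a probability 4-vector")

  eo <- edgesInOutputOrder(tree)
  mats <- vector("list", nrow(eo))
  for (i in seq_len(nrow(eo))) {
    mats[[i]] <- if (eo$length[i] == 0) {
      .identityMatrix(model)
    } else {
      sampleMatrix(model, eo$length[i], maxTrials = maxTrials,
                   edgeLabel = eo$label[i])
    }
  }
  ## matrix lookup by child node id (each node has one parent edge)
  matByChild <- vector("list", max(tree$edge))
  for (i in seq_len(nrow(eo))) matByChild[[eo$child[i]]] <- mats[[i]]@entries

  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- .sampleRootCodes(pi, L)
  for (r in seq_len(nrow(tree$edge))) {      # cladewise = pre-order
    parent <- tree$edge[r, 1]
    child <- tree$edge[r, 2]
    seqs[[child]] <- .evolveCodes(seqs[[parent]], matByChild[[child]])
  }

  aln <- Biostrings::DNAStringSet(vapply(seq_len(ntip), function(i)
    .codesToString(seqs[[i]]), character(1)))
  names(aln) <- tree$tip.label

  internals <- Biostrings::DNAStringSet()
  if (keepInternal) {
    ids <- (ntip + 1L):max(tree$edge)
    internals <- Biostrings::DNAStringSet(vapply(ids, function(i)
      .codesToString(seqs[[i]]), character(1)))
    names(internals) <- paste0("node", ids)
  }

  rec <- new("SimulationRecord",
             modelName        = model@name,
             treeText         = .treeText(tree),
             rootDistribution = unname(pi),
             edgeLabels       = eo$label,
             edgeLengths      = eo$length,
             edgeMatrices     = mats,
             seed             = if (is.null(seed)) NA_integer_
                                else as.integer(seed))
  new("SimulationResult", alignment = aln, record = rec,
      internalSequences = internals)
}

#' @describeIn SimulationResult-class the simulated leaf alignment
#' @export
setMethod("alignment", "SimulationResult", function(x) x@alignment)

#' @describeIn SimulationResult-class the parameters used for the simulation
#' @export
setMethod("simulationRecord", "SimulationResult", function(x) x@record)

#' @describeIn SimulationRecord-class edge substitution matrices in canonical
#'   order
#' @export
setMethod("edgeMatrices", "SimulationRecord", function(x) {
  stats::setNames(x@edgeMatrices, x@edgeLabels)
})

#' @describeIn SimulationRecord-class the root distribution over (A,C,G,T)
#' @export
setMethod("rootDistribution", "SimulationRecord", function(x) {
  stats::setNames(x@rootDistribution, .NUC)
})

#' @describeIn SimulationRecord-class model name of the record
#' @param x a SimulationRecord
#' @export
setMethod("modelName", "SimulationRecord", function(x) x@modelName)

#' @describeIn SimulationRecord-class summary display
#' @param object a SimulationRecord
#' @export
setMethod("show", "SimulationRecord", function(object) {
  cat(sprintf("SimulationRecord: model %s, %d edges, seed %s\n",
              object@modelName, length(object@edgeMatrices),
              ifelse(is.na(object@seed), "<none>", object@seed)))
  cat("root distribution:", sprintf("%.4f", object@rootDistribution), "\n")
  cat("edges:",
      paste(sprintf("%s (%g)", object@edgeLabels, object@edgeLengths),
            collapse = ", "), "\n")
})

#' @describeIn SimulationResult-class summary display
#' @param object a SimulationResult
#' @export
setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d sequences of %d sites (model %s)\n",
              length(object@alignment),
              if (length(object@alignment))
                Biostrings::width(object@alignment)[1] else 0L,
              object@record@modelName))
  show(object@alignment)
})
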