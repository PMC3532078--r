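## Output serialisation: FASTA for the alignment (via Biostrings, 60-column
## wrapping) and a line-oriented plain-text parameter file that is exactly
## re-parseable by readParams(). Matrix entries are printed at 17 significant
## digits so a round trip reproduces every double to the last bit.

#' Write an alignment to FASTA
#'
#' Standard FASTA with 60-column line wrapping; records appear in the
#' alignment's own order (leaf appearance order for simulated alignments).
#'
#' @param aln a `DNAStringSet` or a named character vector of sequences
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeAlignmentFasta <- function(aln, path) {
  if (!is(aln, "XStringSet")) aln <- Biostrings::DNAStringSet(aln)
  Biostrings::writeXStringSet(aln, filepath = path, width = 60L)
  invisible(path)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write simulation parameters to a text file
#'
#' Serialises a [SimulationRecord] to a human-readable, machine-re-parseable
#' text file: model name, seed, input Newick, root distribution, then one
#' block per edge in the canonical order (terminal edges first in leaf
#' appearance order, then internal edges top-down from the root). Each block
#' carries the edge label, its branch length and the 4x4 substitution matrix
#' with rows and columns in A,C,G,T order. Lines starting with '#' are
#' comments.
#'
#' @param rec a [SimulationRecord]
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [readParams()] for the inverse
#' @export
writeParams <- function(rec, path) {
  stopifnot(is(rec, "SimulationRecord"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# simulation parameters (discrete-time Markov models on a tree)")
  w("# matrices are row-stochastic, rows = parent state, columns = child state, order A C G T")
  w("model: %s", rec@modelName)
  w("seed: %s", ifelse(is.na(rec@seed), "NA", as.character(rec@seed)))
  w("tree: %s", rec@treeText)
  w("root_distribution: %s", paste(.fmt(rec@rootDistribution), collapse = " "))
  w("n_edges: %d", length(rec@edgeMatrices))
  for (i in seq_along(rec@edgeMatrices)) {
    w("edge: %s", rec@edgeLabels[i])
    w("length: %s", .fmt(rec@edgeLengths[i]))
    w("matrix:")
    P <- rec@edgeMatrices[[i]]@entries
    for (r in 1:4) w("%s", paste(.fmt(P[r, ]), collapse = " "))
  }
  invisible(path)
}

#' Re-parse a parameter file
#'
#' Reads a file written by [writeParams()] back into a [SimulationRecord];
#' the reconstructed matrices equal the originals to full double precision.
#'
#' @param path parameter file path
#' @return a [SimulationRecord]
#' @export
readParams <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  val <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    if (is.na(hit)) stop(sprintf("parameter file lacks '%s:'", key))
    trimws(sub(paste0("^", key, ":"), "", hit))
  }
  modelName <- val("model")
  seedTxt <- val("seed")
  treeText <- val("tree")
  rootDist <- as.numeric(strsplit(val("root_distribution"), "\\s+")[[1]])
  nEdges <- as.integer(val("n_edges"))
  starts <- grep("^edge:", lines)
  if (length(starts) != nEdges)
    stop(sprintf("expected %d edge blocks, found %d", nEdges, length(starts)))
  labels <- character(nEdges)
  lengths <- numeric(nEdges)
  mats <- vector("list", nEdges)
  for (i in seq_len(nEdges)) {
    at <- starts[i]
    labels[i] <- trimws(sub("^edge:", "", lines[at]))
    lengths[i] <- as.numeric(trimws(sub("^length:", "", lines[at + 1L])))
    rows <- lines[(at + 3L):(at + 6L)]
    P <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    dimnames(P) <- list(.NUC, .NUC)
    mats[[i]] <- new("SubstitutionMatrix", entries = P,
                     modelName = modelName, branchLength = lengths[i])
  }
  new("SimulationRecord",
      modelName        = modelName,
      treeText         = treeText,
      rootDistribution = rootDist,
      edgeLabels       = labels,
      edgeLengths      = lengths,
      edgeMatrices     = mats,
      seed             = if (seedTxt == "NA") NA_integer_
                         else as.integer(seedTxt))
}
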