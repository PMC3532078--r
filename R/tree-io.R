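## Newick input and the canonical edge ordering. Parsing itself is delegated
## to ape::read.tree; this layer enforces the contract the simulator needs:
## every edge carries a positive finite length, leaf names are unique and
## non-empty, and the tree is rooted at the outermost Newick node (where the
## model's root distribution is placed).

.checkParentheses <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed parentheses: unmatched ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed parentheses: %d '(' left unclosed", depth))
  invisible(TRUE)
}

## Tip labels of the clade below an (internal) node, in appearance order.
.cladeTips <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .cladeTips, phy = phy))
}

.edgeChildLabel <- function(phy, child) {
  if (child <= ape::Ntip(phy)) return(phy$tip.label[child])
  paste0("(", paste(.cladeTips(phy, child), collapse = ","), ")")
}

#' Parse a Newick tree with branch lengths
#'
#' Parses a single Newick statement into an [ape::phylo][ape::read.tree] tree,
#' validating the contract the simulator relies on: the statement is
#' terminated by ';', parentheses balance, every edge carries a branch length
#' (in expected substitutions per site), branch lengths are positive and
#' finite, and leaf names are unique and non-empty. Polytomies (nodes of any
#' degree) are accepted; an unrooted tree is treated as rooted at the
#' outermost Newick node, where the root distribution is placed. Internal
#' node labels, if present, are parsed but ignored by the simulator. Child
#' order follows the Newick text (cladewise order).
#'
#' @param text a Newick string, e.g. `"(A:0.1,B:0.2);"`
#' @param allowZeroLength permit zero-length branches (simulated with the
#'   identity matrix) instead of rejecting them
#' @return an `ape` `phylo` object; the original text is kept in
#'   `attr(tree, "newick")`
#' @seealso [readNewickTree()], [edgesInOutputOrder()]
#' @examples
#' tr <- parseNewick(
#'   "((species1:0.01,species2:0.2,species3:0.3):0.5,species4:0.4,species5:0.7);")
#' ape::Ntip(tr)
#' @export
parseNewick <- function(text, allowZeroLength = FALSE) {
  if (!is.character(text) || length(text) != 1L)
    stop("text must be a single Newick string")
  text <- trimws(text)
  if (!nzchar(text) || substring(text, nchar(text)) != ";")
    stop("Newick statement must be terminated by ';'")
  .checkParentheses(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$edge))
    stop("malformed Newick string: could not be parsed")
  if (ape::Ntip(phy) < 2L)
    stop("tree must have at least two leaves")
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (is.null(phy$edge.length))
    stop("missing branch lengths: every edge must carry a ':length' annotation")
  bad <- which(is.na(phy$edge.length))
  if (length(bad)) {
    stop(sprintf("missing branch length on the edge to %s",
                 .edgeChildLabel(phy, phy$edge[bad[1], 2])))
  }
  neg <- which(phy$edge.length < 0 | !is.finite(phy$edge.length))
  if (length(neg)) {
    stop(sprintf("branch length %g on the edge to %s is not a positive number",
                 phy$edge.length[neg[1]],
                 .edgeChildLabel(phy, phy$edge[neg[1], 2])))
  }
  zero <- which(phy$edge.length == 0)
  if (length(zero) && !allowZeroLength) {
    stop(sprintf(paste0(
      "zero-length branch on the edge to %s: a zero branch length forces the ",
      "identity matrix; pass allowZeroLength = TRUE to accept that"),
      .edgeChildLabel(phy, phy$edge[zero[1], 2])))
  }
  if (anyDuplicated(phy$tip.label))
    stop(sprintf("duplicate leaf name '%s'",
                 phy$tip.label[duplicated(phy$tip.label)][1]))
  if (!all(nzchar(phy$tip.label)))
    stop("leaf names must be non-empty")
  attr(phy, "newick") <- text
  phy
}

#' Read a Newick tree from a file
#'
#' Reads the whole file as one Newick statement and parses it with
#' [parseNewick()]. A missing ';' terminator is appended, so a bare
#' `(A:0.1,B:0.2)` tree file is accepted.
#'
#' @param file path to a text file holding one Newick tree
#' @inheritParams parseNewick
#' @return an `ape` `phylo` object
#' @export
readNewickTree <- function(file, allowZeroLength = FALSE) {
  text <- trimws(paste(readLines(file, warn = FALSE), collapse = ""))
  if (!nzchar(text)) stop(sprintf("tree file '%s' is empty", file))
  if (substring(text, nchar(text)) != ";") text <- paste0(text, ";")
  parseNewick(text, allowZeroLength = allowZeroLength)
}

#' Canonical edge ordering for parameter output
#'
#' Lists every edge of the tree exactly once in the order used for the
#' parameter file: terminal edges first, in the order their leaves appear in
#' the Newick text, followed by the internal edges in breadth-first order from
#' the root, siblings in Newick order. Terminal edges are labelled by their
#' leaf name; internal edges by the parenthesised list of leaves below them.
#'
#' @param tree an `ape` `phylo` tree (see [parseNewick()])
#' @return a data.frame with columns `parent`, `child` (ape node ids),
#'   `length`, `label` and `terminal`, one row per edge
#' @examples
#' tr <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' edgesInOutputOrder(tr)$label
#' @export
edgesInOutputOrder <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  len <- tree$edge.length
  ## terminal edges, leaf appearance order = tip numbering order
  termRows <- vapply(seq_len(ntip), function(i) which(edge[, 2] == i),
                     integer(1))
  ## internal edges, BFS from the root, siblings in Newick (edge-matrix) order
  root <- ntip + 1L
  queue <- root
  intRows <- integer(0)
  while (length(queue)) {
    node <- queue[1]
    queue <- queue[-1]
    rows <- which(edge[, 1] == node)
    kids <- edge[rows, 2]
    internal <- kids > ntip
    intRows <- c(intRows, rows[internal])
    queue <- c(queue, kids[internal])
  }
  rows <- c(termRows, intRows)
  data.frame(
    parent   = edge[rows, 1],
    child    = edge[rows, 2],
    length   = len[rows],
    label    = vapply(edge[rows, 2], .edgeChildLabel, character(1), phy = tree),
    terminal = c(rep(TRUE, length(termRows)), rep(FALSE, length(intRows))),
    stringsAsFactors = FALSE
  )
}

## Newick text for a tree: the original input when available, otherwise a
## re-serialisation.
.treeText <- function(tree) {
  txt <- attr(tree, "newick")
  if (is.null(txt)) txt <- ape::write.tree(tree)
  txt
}
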