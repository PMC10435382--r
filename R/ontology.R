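#' Parse a child/parent table into an ontology tree
#'
#' The tree file format is a two-column table: the first column holds every
#' node identifier, the second its parent.  The reserved identifier
#' \code{root} (configurable) in the parent column marks top-level nodes; the
#' root node itself need not appear in the first column.  Children keep their
#' input order; nodes are re-ordered topologically (parents first).
#'
#' @param table a data.frame (or matrix) whose first two columns are child
#'   and parent identifiers.
#' @param codes optional character vector naming the nodes that are observed
#'   disease codes, in the column order of the diagnosis matrix.  Defaults to
#'   all non-root nodes (in topological order).  Nodes present in the tree
#'   but absent from \code{codes} are retained with \code{isCode = FALSE}.
#' @param rootToken identifier used for the root (default \code{"root"}).
#' @return an \linkS4class{OntologyTree}.
#' @examples
#' tab <- data.frame(code = c("A", "A1", "A2"),
#'                   parent = c("root", "A", "A"))
#' parseTree(tab)
#' @export
parseTree <- function(table, codes = NULL, rootToken = "root") {
  table <- as.data.frame(table)
  if (ncol(table) < 2L)
    stop("tree table must have two columns: child, parent")
  child <- as.character(table[[1L]])
  parent <- as.character(table[[2L]])
  keep <- child != rootToken          # tolerate an explicit root row
  child <- child[keep]; parent <- parent[keep]
  if (anyDuplicated(child))
    stop("duplicate child entries: ",
         paste(unique(child[duplicated(child)]), collapse = ", "))
  orphan <- setdiff(parent, c(child, rootToken))
  if (length(orphan))
    stop("orphan parent node(s) never defined as child: ",
         paste(orphan, collapse = ", "))

  # Kahn topological sort, preserving file order among available nodes;
  # any remainder is part of a cycle.
  nodes <- rootToken
  pending <- child
  pendPar <- parent
  while (length(pending)) {
    ready <- pendPar %in% nodes
    if (!any(ready)) {
      cyc <- paste(pending, collapse = " -> ")
      stop("cycle detected among nodes: ", cyc)
    }
    nodes <- c(nodes, pending[ready])
    pending <- pending[!ready]
    pendPar <- pendPar[!ready]
  }
  par <- c(NA_character_, parent[match(nodes[-1L], child)])
  names(par) <- nodes

  if (is.null(codes)) codes <- nodes[-1L]
  if (!all(codes %in% nodes[-1L]))
    stop("codes not present in the tree: ",
         paste(setdiff(codes, nodes[-1L]), collapse = ", "))
  isc <- stats::setNames(nodes %in% codes, nodes)
  new("OntologyTree", nodes = nodes, parent = par, isCode = isc,
      codeOrder = as.character(codes))
}

#' Read / write the two-column tree file
#'
#' Tab- or comma-delimited, two columns \code{code, parent}, optional header
#' (auto-detected by looking for a parent value that never occurs as a child
#' and is not the root token on the first line), UTF-8.
#'
#' @param path file path.
#' @param tree an \linkS4class{OntologyTree}.
#' @param codes,rootToken passed to \code{\link{parseTree}}.
#' @param sep field separator used when writing (default tab).
#' @return \code{readTreeFile}: an \linkS4class{OntologyTree};
#'   \code{writeTreeFile}: the path, invisibly.
#' @export
readTreeFile <- function(path, codes = NULL, rootToken = "root") {
  first <- strsplit(readLines(path, n = 1L), "[\t,]")[[1L]]
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  header <- identical(tolower(first[1:2]), c("code", "parent"))
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  parseTree(tab, codes = codes, rootToken = rootToken)
}

#' @rdname readTreeFile
#' @export
writeTreeFile <- function(tree, path, sep = "\t") {
  stopifnot(is(tree, "OntologyTree"))
  nd <- nodeNames(tree)[-1L]
  utils::write.table(
    data.frame(code = nd, parent = parentMap(tree)[nd]),
    path, sep = sep, quote = FALSE, row.names = FALSE, col.names = TRUE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Flatten a tree to a star over its codes
#'
#' Returns the non-informative prior tree used by flatLFA: every code node
#' is placed directly under the common root; non-code internal nodes are
#' dropped.  The code ordering is preserved, so a fitted flat model is
#' column-compatible with the original tree's diagnosis matrix.
#'
#' @param tree an \linkS4class{OntologyTree}.
#' @return an \linkS4class{OntologyTree} of depth 1.
#' @export
flattenTree <- function(tree) {
  stopifnot(is(tree, "OntologyTree"))
  root <- rootName(tree)
  codes <- codeNames(tree)
  nodes <- c(root, codes)
  par <- c(NA_character_, rep(root, length(codes)))
  names(par) <- nodes
  isc <- stats::setNames(c(FALSE, rep(TRUE, length(codes))), nodes)
  new("OntologyTree", nodes = nodes, parent = par, isCode = isc,
      codeOrder = codes)
}

#' The fixed simulation tree
#'
#' A three-layer tree over 20 disease codes: the root, five second-layer
#' codes \code{P1..P5}, each with three third-layer children
#' \code{P<i>.1..P<i>.3}.  All 20 non-root nodes are observed codes; the
#' code order is branch by branch, parent first.
#'
#' @return an \linkS4class{OntologyTree} with 21 nodes.
#' @examples
#' tr <- buildSimTree()
#' length(codeNames(tr))   # 20
#' @export
buildSimTree <- function() {
  parents <- paste0("P", 1:5)
  rows <- do.call(rbind, lapply(parents, function(p) {
    rbind(c(p, "root"),
          cbind(paste0(p, ".", 1:3), p))
  }))
  tab <- data.frame(code = rows[, 1L], parent = rows[, 2L])
  # code order: branch by branch, parent before children
  ord <- unlist(lapply(parents, function(p) c(p, paste0(p, ".", 1:3))))
  parseTree(tab, codes = ord)
}

# depth of every node (root = 0)
treeDepths <- function(tree) {
  nd <- tree@nodes
  d <- stats::setNames(integer(length(nd)), nd)
  for (n in nd[-1L]) d[n] <- d[tree@parent[n]] + 1L
  d
}

# Integer encoding of a tree for the C++ kernels: 0-based node indices in
# topological order (root = 0), parent index per node, CSR children lists,
# and the code-column index (-1 for non-code nodes).
treeIndex <- function(tree) {
  nd <- nodeNames(tree)
  M <- length(nd)
  idx <- stats::setNames(seq_len(M) - 1L, nd)
  parentIdx <- c(-1L, idx[tree@parent[nd[-1L]]])
  kidsOf <- lapply(nd, function(n) idx[names(tree@parent)[
    !is.na(tree@parent) & tree@parent == n]])
  childStart <- cumsum(c(0L, vapply(kidsOf, length, 0L)))
  codeIdx <- rep(-1L, M)
  codeIdx[idx[codeNames(tree)] + 1L] <- seq_along(codeNames(tree)) - 1L
  list(parent = as.integer(parentIdx),
       childStart = as.integer(childStart),
       childList = as.integer(unlist(kidsOf)),
       codeIdx = as.integer(codeIdx),
       nNodes = M)
}

#' Binary group indicators from internal tree nodes
#'
#' For every internal (non-leaf, non-root) node, a binary vector over the
#' code order marking its descendant codes.  Used for the ontology
#' concordance metric, where topics are correlated with expert-defined
#' disease groups such as chapters and blocks.
#'
#' @param tree an \linkS4class{OntologyTree}.
#' @return a binary matrix (groups x codes) with group row names.
#' @export
groupIndicators <- function(tree) {
  nd <- nodeNames(tree)
  kids <- childrenMap(tree)
  internal <- setdiff(names(kids)[vapply(kids, length, 0L) > 0L],
                      rootName(tree))
  codes <- codeNames(tree)
  desc <- function(n) {
    out <- character()
    stack <- kids[[n]]
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      out <- c(out, x)
      if (!is.null(kids[[x]])) stack <- c(stack, kids[[x]])
    }
    c(n, out)
  }
  G <- t(vapply(internal,
                function(n) as.integer(codes %in% desc(n)),
                integer(length(codes))))
  if (length(internal) == 0L)
    G <- matrix(0L, 0L, length(codes))
  rownames(G) <- internal
  colnames(G) <- codes
  G
}
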