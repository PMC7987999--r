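#' Node ages of an ultrametric tree
#'
#' Ages in years before present for every node of a dated (ultrametric)
#' tree: tips at 0, internal nodes at their coalescence times. Indexing
#' follows the \pkg{ape} convention (tips \code{1..n}, then internal
#' nodes).
#'
#' @param tree a rooted \code{phylo} with branch lengths in years.
#' @return numeric vector of length \code{Ntip + Nnode}.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (nrow(tree$edge) == 0L) return(numeric(n))
  d <- ape::node.depth.edgelength(tree)
  a <- max(d[seq_len(n)]) - d
  a[abs(a) < 1e-9] <- 0
  a
}

#' Descendant tips of every node
#'
#' @param tree a rooted \code{phylo}.
#' @return list of sorted tip indices, one element per node (tips map to
#'   themselves).
#' @export
tips_under <- function(tree) {
  n <- length(tree$tip.label)
  res <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) res[[i]] <- i
  if (nrow(tree$edge) == 0L) return(res)
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (j in seq_len(nrow(eo))) {
    p <- eo[j, 1L]
    res[[p]] <- c(res[[p]], res[[eo[j, 2L]]])
  }
  lapply(res, sort)
}

# parent of every node (0 for the root), ape indexing
parent_vec <- function(tree) {
  n <- length(tree$tip.label)
  p <- integer(n + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# children of every node as a list
children_list <- function(tree) {
  n <- length(tree$tip.label)
  ch <- vector("list", n + tree$Nnode)
  for (j in seq_len(nrow(tree$edge)))
    ch[[tree$edge[j, 1L]]] <- c(ch[[tree$edge[j, 1L]]], tree$edge[j, 2L])
  ch
}

root_node <- function(tree) {
  length(tree$tip.label) + 1L
}

# path of nodes from the root down to (and including) `node`
root_path <- function(tree, node) {
  p <- parent_vec(tree)
  path <- node
  while (p[node] != 0L) {
    node <- p[node]
    path <- c(node, path)
  }
  path
}
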