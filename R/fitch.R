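#' Minimum state changes of binary sites on a tree
#'
#' Small-parsimony score of binary (0/1) characters on a rooted tree,
#' computed with the Fitch/Hartigan bottom-up pass (exact also at
#' polytomies). Missing calls are wildcards compatible with either state.
#' Sites monomorphic among the scored tips need 0 changes; a site fully
#' compatible with one branch needs 1.
#'
#' @param tree rooted \code{phylo} whose tip labels cover the matrix
#'   columns used.
#' @param geno integer matrix (sites x tips, 0/1/NA) with column names
#'   matching \code{tree$tip.label}.
#' @return integer vector of minimum change counts, one per site.
#' @export
fitch_changes <- function(tree, geno) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)) || !all(tree$tip.label %in% colnames(geno)))
    stop("matrix columns must cover all tree tips")
  geno <- geno[, tree$tip.label, drop = FALSE]
  ns <- nrow(geno)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  if (ns == 0L) return(integer(0))
  # candidate-state indicators per node, vectorized over sites
  can0 <- matrix(FALSE, ns, nn)
  can1 <- matrix(FALSE, ns, nn)
  can0[, seq_len(n)] <- is.na(geno) | geno == 0L
  can1[, seq_len(n)] <- is.na(geno) | geno == 1L
  changes <- integer(ns)
  ch <- children_list(tree)
  ord <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
  for (p in ord) {
    kids <- ch[[p]]
    v0 <- rowSums(can0[, kids, drop = FALSE])
    v1 <- rowSums(can1[, kids, drop = FALSE])
    mx <- pmax(v0, v1)
    changes <- changes + length(kids) - mx
    can0[, p] <- v0 == mx
    can1[, p] <- v1 == mx
  }
  as.integer(changes)
}

#' Parsimony placement of one binary site
#'
#' Top-down completion of the Fitch/Hartigan pass for a single site:
#' assigns a most-parsimonious state to every node (preferring the
#' ancestral state 0 at ties, consistent with outgroup polarization) and
#' returns the branches (child nodes) on which 0 -> 1 or 1 -> 0 changes
#' occur.
#'
#' @inheritParams fitch_changes
#' @param states integer vector of 0/1/NA tip states named by tip label.
#' @return list with \code{changes} (count), \code{branches} (child node
#'   ids of mutated branches) and \code{node_states}.
#' @export
fitch_placement <- function(tree, states) {
  geno <- matrix(states, 1, length(states),
                 dimnames = list(NULL, names(states)))
  geno <- geno[, tree$tip.label, drop = FALSE]
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  can0 <- can1 <- logical(nn)
  can0[seq_len(n)] <- is.na(geno[1, ]) | geno[1, ] == 0L
  can1[seq_len(n)] <- is.na(geno[1, ]) | geno[1, ] == 1L
  ch <- children_list(tree)
  ord <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
  for (p in ord) {
    kids <- ch[[p]]
    v0 <- sum(can0[kids]); v1 <- sum(can1[kids])
    mx <- max(v0, v1)
    can0[p] <- v0 == mx
    can1[p] <- v1 == mx
  }
  state <- integer(nn)
  rt <- root_node(tree)
  state[rt] <- if (can0[rt]) 0L else 1L
  branches <- integer(0)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (j in seq_len(nrow(pre))) {
    p <- pre[j, 1L]; cnode <- pre[j, 2L]
    ps <- state[p]
    ok <- if (ps == 0L) can0[cnode] else can1[cnode]
    if (ok) {
      state[cnode] <- ps
    } else {
      state[cnode] <- 1L - ps
      branches <- c(branches, cnode)
    }
  }
  list(changes = length(branches), branches = branches,
       node_states = state)
}
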