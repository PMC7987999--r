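#' Build a haplotree by perfect-phylogeny construction
#'
#' On binary, nearly homoplasy-free Y-chromosome data the rooted topology
#' is determined by site compatibility, so the tree is built directly
#' from carrier sets: each site's set of derived-allele carriers proposes
#' a clade; clades are accepted greedily in order of support (number of
#' identical sites, then size) as long as they stay pairwise nested or
#' disjoint (a laminar family); sites whose carrier set is rejected are
#' homoplasy and handled downstream as recurrent. Missing calls do not
#' count as carriers. If an outgroup column is supplied, sites derived in
#' the outgroup are repolarized and the outgroup roots the tree as sister
#' to the ingroup.
#'
#' @param gm a \code{\link{geno_matrix}} (or plain 0/1/NA site x sample
#'   matrix).
#' @param outgroup optional outgroup sample name.
#' @return a rooted \code{phylo}; polytomies are retained, identical
#'   samples appear as sister tips.
#' @export
build_parsimony_tree <- function(gm, outgroup = NULL) {
  geno <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  samples <- colnames(geno)
  allmiss <- samples[colSums(!is.na(geno)) == 0L & nrow(geno) > 0L]
  if (length(allmiss))
    stop("sample(s) with no called sites: ", paste(allmiss, collapse = ", "))
  if (!is.null(outgroup)) {
    if (!outgroup %in% samples) stop("outgroup sample not in matrix")
    og <- geno[, outgroup]
    flip <- !is.na(og) & og == 1L
    geno[flip, ] <- 1L - geno[flip, ]
    geno <- geno[, setdiff(samples, outgroup), drop = FALSE]
    samples <- colnames(geno)
  }
  n <- length(samples)
  carriers <- apply(geno == 1L & !is.na(geno), 1L, which, simplify = FALSE)
  keys <- vapply(carriers, paste, "", collapse = ",")
  nonempty <- lengths(carriers) > 0L
  tab <- table(keys[nonempty])
  uk <- names(tab)
  usets <- lapply(strsplit(uk, ","), as.integer)
  ord <- order(-as.integer(tab), lengths(usets), uk)
  accepted <- list()
  acc_mat <- matrix(FALSE, 0, n)
  for (i in ord) {
    s <- usets[[i]]
    v <- logical(n); v[s] <- TRUE
    ok <- TRUE
    if (nrow(acc_mat)) {
      inter <- acc_mat[, s, drop = FALSE]
      ni <- rowSums(inter)
      sz <- rowSums(acc_mat)
      # nested or disjoint with every accepted clade
      ok <- all(ni == 0L | ni == length(s) | ni == sz)
    }
    if (ok) {
      accepted[[length(accepted) + 1L]] <- s
      acc_mat <- rbind(acc_mat, v)
    }
  }
  # ensure the full ingroup clade exists as root
  if (!any(vapply(accepted, length, 1L) == n))
    accepted[[length(accepted) + 1L]] <- seq_len(n)
  accepted <- accepted[order(lengths(accepted))]
  sizes <- lengths(accepted)
  nclade <- length(accepted)
  parent <- integer(nclade)
  for (i in seq_len(nclade)) {
    parent[i] <- 0L
    if (i < nclade) for (j in seq((i + 1L), nclade)) {
      if (all(accepted[[i]] %in% accepted[[j]]) && sizes[j] > sizes[i]) {
        parent[i] <- j
        break
      }
    }
  }
  tip_parent <- integer(n)
  for (t in seq_len(n))
    tip_parent[t] <- which(vapply(accepted,
                                  function(s) t %in% s, TRUE))[1L]
  esc <- function(x) gsub("[(),:;\\s]", "_", x, perl = TRUE)
  build <- function(ci) {
    kids_c <- which(parent == ci)
    kids_t <- which(tip_parent == ci)
    parts <- c(vapply(kids_c, build, ""), esc(samples[kids_t]))
    if (length(parts) == 1L) return(parts)   # collapse unifurcations
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rootc <- which(sizes == n)[1L]
  nwk <- build(rootc)
  if (!is.null(outgroup)) {
    nwk <- if (startsWith(nwk, "(")) paste0("(", nwk, ",", esc(outgroup), ")")
           else paste0("((", nwk, "),", esc(outgroup), ")")
  } else if (!startsWith(nwk, "(")) {
    nwk <- paste0("(", nwk, ")")
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Assign every site to a branch of the haplotree
#'
#' A site whose carrier set equals the descendant tip set of exactly one
#' branch is assigned to that branch (missing calls act as wildcards;
#' ambiguous matches resolve toward the smaller carrier set). Sites whose
#' carriers match no branch receive a minimal multi-origin
#' Fitch/Hartigan placement and are counted recurrent.
#'
#' @param tree rooted \code{phylo} whose tips are matrix samples.
#' @param gm a \code{\link{geno_matrix}}.
#' @return object of class \code{site_assignment}: data.frame
#'   (\code{pos}, \code{branch} = child node id, \code{recurrent});
#'   attributes \code{recurrent_branches} (list of branch vectors),
#'   \code{recurrence_fraction}, \code{n_single}, \code{n_recurrent}.
#' @export
map_sites_to_branches <- function(tree, gm) {
  geno <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  pos <- if (inherits(gm, "geno_matrix")) gm$pos else seq_len(nrow(geno))
  if (!all(tree$tip.label %in% colnames(geno)))
    stop("tree tips must be matrix samples")
  geno <- geno[, tree$tip.label, drop = FALSE]
  n <- length(tree$tip.label)
  tu <- tips_under(tree)
  nn <- n + tree$Nnode
  N <- matrix(FALSE, nn, n)
  for (v in seq_len(nn)) N[v, tu[[v]]] <- TRUE
  csize <- rowSums(N)
  ns <- nrow(geno)
  branch <- rep(NA_integer_, ns)
  recurrent <- logical(ns)
  rec_br <- list()
  Ones <- t(geno == 1L & !is.na(geno)) * 1
  Zeros <- t(geno == 0L & !is.na(geno)) * 1
  cov1 <- N %*% Ones                    # carriers inside node's tip set
  cov0 <- N %*% Zeros                   # ancestral samples inside it
  tot1 <- colSums(Ones)
  for (s in seq_len(ns)) {
    if (tot1[s] == 0L) next            # monomorphic: no branch
    cand <- which(cov1[, s] == tot1[s] & cov0[, s] == 0)
    if (length(cand)) {
      branch[s] <- cand[which.min(csize[cand])]
    } else {
      st <- geno[s, ]; names(st) <- tree$tip.label
      fp <- fitch_placement(tree, st)
      recurrent[s] <- TRUE
      branch[s] <- NA_integer_
      rec_br[[as.character(s)]] <- fp$branches
    }
  }
  out <- data.frame(pos = pos, branch = branch, recurrent = recurrent)
  attr(out, "recurrent_branches") <- rec_br
  attr(out, "n_single") <- sum(!recurrent & !is.na(branch))
  attr(out, "n_recurrent") <- sum(recurrent)
  attr(out, "recurrence_fraction") <- if (ns) sum(recurrent) / ns else 0
  class(out) <- c("site_assignment", "data.frame")
  out
}

#' Per-branch SNP counts for the dating likelihood
#'
#' @param tree rooted \code{phylo}.
#' @param assignment a \code{\link{map_sites_to_branches}} result.
#' @param include_recurrent count each origin of a recurrent site on its
#'   Fitch branch (default \code{FALSE}).
#' @return numeric vector aligned with \code{tree$edge} rows.
#' @export
snp_counts_from_assignment <- function(tree, assignment,
                                       include_recurrent = FALSE) {
  counts <- integer(length(tree$tip.label) + tree$Nnode)
  single <- assignment$branch[!assignment$recurrent &
                                !is.na(assignment$branch)]
  t1 <- tabulate(single, nbins = length(counts))
  counts <- counts + t1
  if (include_recurrent)
    for (br in attr(assignment, "recurrent_branches"))
      counts[br] <- counts[br] + 1L
  counts[tree$edge[, 2L]]
}
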