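#' Panel of phylogenetically informative SNPs
#'
#' Extracts the single-origin branch-defining sites of an assigned
#' haplotree as a placement panel; recurrent sites are excluded.
#'
#' @param tree rooted \code{phylo}.
#' @param assignment a \code{\link{map_sites_to_branches}} result.
#' @param ancestral,derived allele letters used when the matrix carries
#'   none (defaults "A"/"G").
#' @return object of class \code{snp_panel}: data.frame with \code{pos},
#'   \code{ancestral}, \code{derived}, \code{branch} (child node id).
#' @export
informative_site_panel <- function(tree, assignment,
                                   ancestral = "A", derived = "G") {
  if (is.null(assignment) || !inherits(assignment, "site_assignment"))
    stop("tree has no site-to-branch assignments; run map_sites_to_branches")
  ok <- !assignment$recurrent & !is.na(assignment$branch)
  out <- data.frame(pos = assignment$pos[ok],
                    ancestral = ancestral, derived = derived,
                    branch = assignment$branch[ok])
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Read panel alleles off an observation table
#'
#' Matches per-position allele observations (e.g. extracted from an
#' ancient sample's pileup) against a placement panel: a panel site is
#' derived/ancestral when its observed allele equals the panel allele at
#' sufficient depth, missing otherwise; alleles matching neither panel
#' allele count as mismatches and become missing.
#'
#' @param observation_table data.frame with columns \code{pos},
#'   \code{allele}, \code{depth}.
#' @param panel a \code{\link{informative_site_panel}} result.
#' @param min_depth minimum read depth to call a site (default 1).
#' @return an \code{ancient_observation} (state 0/1/NA per panel site,
#'   with a \code{n_mismatch} element).
#' @export
observe_alleles <- function(observation_table, panel, min_depth = 1) {
  tb <- observation_table
  need <- c("pos", "allele", "depth")
  if (!all(need %in% names(tb)))
    stop("observation table must have columns pos, allele, depth")
  bad <- which(!is.finite(suppressWarnings(as.numeric(tb$pos))) |
                 is.na(tb$allele) | tb$allele == "" |
                 !is.finite(suppressWarnings(as.numeric(tb$depth))))
  if (length(bad))
    stop("malformed observation rows: ", paste(bad, collapse = ", "))
  tb <- tb[as.numeric(tb$depth) >= min_depth, , drop = FALSE]
  tb <- tb[order(-as.numeric(tb$depth)), , drop = FALSE]
  tb <- tb[!duplicated(tb$pos), , drop = FALSE]   # deepest call per site
  hit <- match(panel$pos, tb$pos)
  st <- rep(NA_integer_, nrow(panel))
  obs_allele <- tb$allele[hit]
  st[!is.na(hit) & obs_allele == panel$derived] <- 1L
  st[!is.na(hit) & obs_allele == panel$ancestral] <- 0L
  n_mismatch <- sum(!is.na(hit) & obs_allele != panel$derived &
                      obs_allele != panel$ancestral)
  if (n_mismatch > 0)
    warning(n_mismatch, " observed allele(s) match neither panel allele")
  structure(list(state = st, pos = panel$pos, truth_branch = NULL,
                 n_mismatch = n_mismatch),
            class = "ancient_observation")
}

#' Place a (possibly ancient) sample on the haplotree
#'
#' Branch support is scored from the panel sites owned by each branch:
#' a branch is supported when derived calls outnumber ancestral calls,
#' contradicted when the reverse holds, and pass-through when none of its
#' sites were observed. The sample is affiliated to the deepest supported
#' branch whose path from the root contains no contradicted branch; a
#' derived call at a site defining a sister of the assigned branch
#' degrades the assignment to the parent node. With no supported branch
#' anywhere the sample is unassigned. In \code{strict} mode any
#' ancestral call blocks a branch.
#'
#' @param obs an \code{ancient_observation} over the panel sites.
#' @param tree rooted \code{phylo}.
#' @param panel the \code{\link{informative_site_panel}} used.
#' @param rule \code{"majority"} (default) or \code{"strict"}.
#' @return object of class \code{affiliation}: list with \code{branch}
#'   (node id or NA), \code{status} (\code{assigned},
#'   \code{degraded_to_parent} or \code{unassigned}), \code{path},
#'   \code{support} (per-branch derived/ancestral/missing counts),
#'   \code{sister_conflicts}.
#' @export
place_sample <- function(obs, tree, panel, rule = c("majority", "strict")) {
  rule <- match.arg(rule)
  nn <- length(tree$tip.label) + tree$Nnode
  nd <- tabulate(panel$branch[!is.na(obs$state) & obs$state == 1L],
                 nbins = nn)
  na_ <- tabulate(panel$branch[!is.na(obs$state) & obs$state == 0L],
                  nbins = nn)
  nm <- tabulate(panel$branch[is.na(obs$state)], nbins = nn)
  supported <- if (rule == "majority") nd > na_ else nd > 0L & na_ == 0L
  contradicted <- if (rule == "majority") na_ > nd else na_ > 0L
  pv <- parent_vec(tree)
  depth <- integer(nn)
  rt <- root_node(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (j in seq_len(nrow(pre)))
    depth[pre[j, 2L]] <- depth[pre[j, 1L]] + 1L

  path_clean <- function(v) {
    while (v != rt) {
      if (contradicted[v]) return(FALSE)
      v <- pv[v]
    }
    TRUE
  }
  cand <- which(supported)
  cand <- cand[vapply(cand, path_clean, TRUE)]
  mk <- function(branch, status, sister_conflicts = 0L) {
    path <- if (!is.na(branch)) root_path(tree, branch) else integer(0)
    structure(list(branch = branch, status = status, path = path,
                   support = data.frame(node = path,
                                        derived = nd[path],
                                        ancestral = na_[path],
                                        missing = nm[path]),
                   sister_conflicts = sister_conflicts),
              class = "affiliation")
  }
  if (!length(cand)) return(mk(NA_integer_, "unassigned"))
  best <- cand[order(-depth[cand],
                     -vapply(cand, function(v)
                       sum(supported[root_path(tree, v)]), 1L),
                     cand)][1L]
  sisters <- setdiff(children_list(tree)[[pv[best]]], best)
  conflicts <- sum(nd[sisters])
  if (conflicts > 0L) {
    parent <- pv[best]
    return(mk(if (parent == 0L) NA_integer_ else parent,
              "degraded_to_parent", conflicts))
  }
  mk(best, "assigned")
}

#' @export
print.affiliation <- function(x, ...) {
  cat("affiliation:", x$status,
      if (!is.na(x$branch)) paste0("(node ", x$branch, ")"), "\n")
  invisible(x)
}
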