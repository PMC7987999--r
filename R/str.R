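#' Default Y-STR locus panel used for diversity estimates
#' @export
YSTR_LOCI <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391",
               "DYS392", "DYS393", "DYS439")

#' Simulate stepwise-mutation STR haplotypes on a tree
#'
#' Each locus evolves independently along branches under the stepwise
#' mutation model: mutations arrive as a Poisson process at
#' \code{str_rate} per locus per generation and change the repeat count by
#' +1 or -1 with equal probability, with a reflecting boundary at
#' \code{floor} repeats (a step below the floor bounces back).
#'
#' @param tree dated \code{phylo} (branch lengths in years).
#' @param n_loci number of loci (8 gives the canonical DYS panel names).
#' @param str_rate mutations per locus per generation.
#' @param generation_time years per generation (default 31).
#' @param seed integer seed.
#' @param root_haplotype integer repeat counts at the root (default 14
#'   at every locus, a typical modal Y-STR allele).
#' @param floor smallest attainable repeat count (default 1).
#' @return object of class \code{str_table}: list with \code{repeats}
#'   (tips x loci integer matrix), \code{node_repeats} (all nodes),
#'   \code{loci}, and \code{n_mutations} (total mutation count per locus).
#' @export
simulate_str_haplotypes <- function(tree, n_loci = 8, str_rate = 0.002,
                                    generation_time = 31, seed = 1L,
                                    root_haplotype = NULL, floor = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (str_rate < 0) stop("str_rate must be >= 0")
  loci <- if (n_loci == 8) YSTR_LOCI else sprintf("STR%02d", seq_len(n_loci))
  if (is.null(root_haplotype)) root_haplotype <- rep(14L, n_loci)
  stopifnot(length(root_haplotype) == n_loci)
  set.seed(.yc_check_seed(seed))
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  rep_mat <- matrix(rep(as.integer(root_haplotype), each = nn), nn, n_loci,
                    dimnames = list(NULL, loci))
  nmut <- setNames(integer(n_loci), loci)
  if (nrow(tree$edge) > 0L) {
    tr <- ape::reorder.phylo(tree, "cladewise")
    gens <- tr$edge.length / generation_time
    for (j in seq_len(nrow(tr$edge))) {
      p <- tr$edge[j, 1L]; ch <- tr$edge[j, 2L]
      rep_mat[ch, ] <- rep_mat[p, ]
      k <- rpois(n_loci, str_rate * gens[j])
      nmut <- nmut + k
      for (l in which(k > 0L)) {
        v <- rep_mat[ch, l]
        steps <- sample(c(-1L, 1L), k[l], replace = TRUE)
        for (s in steps) {
          v <- v + s
          if (v < floor) v <- 2L * floor - v   # reflecting boundary
        }
        rep_mat[ch, l] <- v
      }
    }
  }
  structure(list(repeats = rep_mat[seq_len(n), , drop = FALSE] |>
                   `rownames<-`(tree$tip.label),
                 node_repeats = rep_mat, loci = loci, n_mutations = nmut),
            class = "str_table")
}

#' @export
print.str_table <- function(x, ...) {
  cat("str_table:", nrow(x$repeats), "haplotypes x", length(x$loci),
      "loci\n")
  invisible(x)
}
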