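#' Drop infinite-sites mutations on a dated genealogy
#'
#' Poisson mutation process along branches: branch \code{b} of duration
#' \code{t_b} years receives \code{Poisson(mu * L * t_b)} mutations, each
#' at a unique uniformly drawn position in \code{[1, L]}. Carriers of a
#' mutation are exactly the tip descendants of its branch, so the
#' resulting matrix is homoplasy-free (a perfect phylogeny).
#'
#' @param tree dated ultrametric \code{phylo} (branch lengths in years).
#' @param mu mutation rate per base per year (>= 0).
#' @param L callable length in bases.
#' @param seed integer seed.
#' @return list with components \code{matrix} (a
#'   \code{\link{geno_matrix}}) and \code{truth} (data.frame of
#'   \code{pos}, \code{branch} = ape child-node id of the carrying
#'   branch), both ordered by position.
#' @export
drop_mutations <- function(tree, mu, L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (mu < 0) stop("mu must be >= 0")
  if (L <= 0) stop("L must be positive")
  n <- length(tree$tip.label)
  empty <- function() {
    gm <- geno_matrix(matrix(integer(0), 0, n,
                             dimnames = list(NULL, tree$tip.label)),
                      numeric(0), samples = tree$tip.label,
                      mask = region_mask(0, L))
    list(matrix = gm, truth = data.frame(pos = numeric(0),
                                         branch = integer(0)))
  }
  if (mu == 0 || nrow(tree$edge) == 0L) return(empty())
  set.seed(.yc_check_seed(seed))
  nb <- rpois(nrow(tree$edge), mu * L * tree$edge.length)
  S <- sum(nb)
  if (S == 0L) return(empty())
  if (S > L) stop("more mutations than available positions; increase L")
  pos <- sample.int(L, S)              # unique positions
  branch <- rep(tree$edge[, 2L], nb)   # child node of each mutation's branch
  o <- order(pos)
  pos <- pos[o]; branch <- branch[o]
  tu <- tips_under(tree)
  geno <- matrix(0L, S, n, dimnames = list(NULL, tree$tip.label))
  for (i in seq_len(S)) geno[i, tu[[branch[i]]]] <- 1L
  gm <- geno_matrix(geno, pos, samples = tree$tip.label,
                    mask = region_mask(0, L))
  list(matrix = gm, truth = data.frame(pos = as.numeric(pos),
                                       branch = branch))
}
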