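#' Piecewise-constant demographic model
#'
#' Effective population size as a step function of time before present,
#' used as the intensity of the Kingman coalescent. Epoch \code{i} applies
#' from \code{times[i]} (years BP) until the next epoch start; the last
#' epoch extends to infinity.
#'
#' @param Ne effective population sizes (individuals), one per epoch.
#' @param times epoch start times in years BP; must begin at 0 and be
#'   strictly increasing.
#' @param generation_time male generation time in years (default 31).
#' @return an object of class \code{demography_model}.
#' @export
demography_model <- function(Ne, times = 0, generation_time = 31) {
  if (length(Ne) != length(times))
    stop("'Ne' and 'times' must have the same length")
  if (times[1] != 0 || (length(times) > 1 && any(diff(times) <= 0)))
    stop("epoch start times must strictly increase from 0")
  if (any(!is.finite(Ne)) || any(Ne <= 0))
    stop("all Ne must be positive and finite")
  if (!is.finite(generation_time) || generation_time <= 0)
    stop("generation_time must be positive")
  structure(list(Ne = as.numeric(Ne), times = as.numeric(times),
                 generation_time = as.numeric(generation_time)),
            class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat("Piecewise-constant demography (", length(x$Ne), " epoch(s), g = ",
      x$generation_time, " yr)\n", sep = "")
  print(data.frame(start_years_bp = x$times, Ne = x$Ne))
  invisible(x)
}

# waiting time for one coalescence: k lineages, starting at time t0,
# piecewise-constant Ne; inverts the cumulative hazard against an Exp(1) draw
piecewise_coal_wait <- function(t0, k, dem, E) {
  cc <- k * (k - 1) / 2
  g <- dem$generation_time
  m <- length(dem$Ne)
  i <- findInterval(t0, dem$times)
  t <- t0
  repeat {
    r <- cc / (2 * dem$Ne[i] * g)       # per-year coalescence rate
    if (i == m) return(t + E / r)
    cap <- (dem$times[i + 1] - t) * r
    if (E <= cap) return(t + E / r)
    E <- E - cap
    t <- dem$times[i + 1]
    i <- i + 1L
  }
}

#' Simulate a dated genealogy under the Kingman coalescent
#'
#' Draws a binary rooted ultrametric genealogy of \code{n_samples} present
#' day lineages under a piecewise-constant effective-population-size model:
#' while \code{k} lineages survive at time \code{t}, the next coalescence
#' occurs at rate \code{choose(k, 2) / (2 * Ne(t) * g)} per year (the
#' standard coalescent time scale of 2Ne generations, so a pair of
#' lineages coalesces after 2Ne generations in expectation), and two
#' uniformly chosen lineages merge. Branch lengths are in years.
#'
#' @param n_samples number of sampled chromosomes (tips), >= 1.
#' @param demography a \code{\link{demography_model}}.
#' @param seed integer seed; identical seeds give identical trees.
#' @return an ultrametric \code{phylo}; for \code{n_samples = 1} a
#'   degenerate single-tip tree with no internal nodes.
#' @export
simulate_genealogy <- function(n_samples,
                               demography = demography_model(10000),
                               seed = 1L) {
  if (!inherits(demography, "demography_model"))
    demography <- do.call(demography_model, as.list(demography))
  if (n_samples < 1) stop("n_samples must be >= 1")
  n <- as.integer(n_samples)
  tip.label <- sprintf("S%03d", seq_len(n))
  if (n == 1L)
    return(structure(list(edge = matrix(integer(0), 0, 2),
                          edge.length = numeric(0),
                          tip.label = tip.label, Nnode = 0L),
                     class = "phylo"))
  set.seed(.yc_check_seed(seed))
  age <- numeric(2L * n - 1L)
  active <- seq_len(n)
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  t <- 0
  ei <- 0L
  for (j in seq_len(n - 1L)) {
    k <- length(active)
    t <- piecewise_coal_wait(t, k, demography, rexp(1))
    pick <- sample.int(k, 2L)
    nid <- 2L * n - j                  # last merge (root) lands on n + 1
    age[nid] <- t
    for (child in active[pick]) {
      ei <- ei + 1L
      edges[ei, ] <- c(nid, child)
      elen[ei] <- t - age[child]
    }
    active <- c(active[-pick], nid)
  }
  tr <- structure(list(edge = edges, edge.length = elen,
                       tip.label = tip.label, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}
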