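#' Degrade a genotype vector into an ancient-style observation
#'
#' Emulates a low-coverage ancient sample: each site independently becomes
#' missing with probability \code{missing_rate}; surviving calls flip
#' state (ancestral <-> derived) with probability \code{error_rate}.
#' Errors are symmetric; strand-specific deamination profiles are out of
#' scope.
#'
#' @param genotypes integer vector of 0/1/NA calls (one sample).
#' @param missing_rate,error_rate probabilities in [0, 1].
#' @param seed integer seed.
#' @param pos optional site positions carried through.
#' @param truth_branch optional true branch (child node id) for scoring.
#' @return object of class \code{ancient_observation}: list with
#'   \code{state} (0/1/NA), \code{pos}, \code{truth_branch}.
#' @export
degrade_sample <- function(genotypes, missing_rate, error_rate, seed = 1L,
                           pos = NULL, truth_branch = NULL) {
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1)
    stop("rates must lie in [0, 1]")
  set.seed(.yc_check_seed(seed))
  st <- as.integer(genotypes)
  nsite <- length(st)
  miss <- runif(nsite) < missing_rate
  flip <- runif(nsite) < error_rate
  st[miss] <- NA_integer_
  doflip <- !is.na(st) & flip
  st[doflip] <- 1L - st[doflip]
  structure(list(state = st, pos = pos, truth_branch = truth_branch),
            class = "ancient_observation")
}

#' @export
print.ancient_observation <- function(x, ...) {
  cat("ancient_observation:", length(x$state), "sites;",
      sum(is.na(x$state)), "missing\n")
  invisible(x)
}
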