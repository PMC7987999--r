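#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least \code{prob} of the
#' sorted samples (leftmost interval on ties).
#'
#' @param samples numeric vector (>= 2 finite values).
#' @param prob coverage level (default 0.95).
#' @return numeric \code{c(lo, hi)}.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (n < 2L) stop("need at least 2 finite samples")
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1L], x[n]))
  w <- x[seq(m, n)] - x[seq_len(n - m + 1L)]
  i <- which.min(w)                     # which.min takes the leftmost tie
  c(x[i], x[i + m - 1L])
}

#' Combine MCMC chains after burn-in
#'
#' Drops the first \code{burnin_fraction} of every trace and concatenates
#' the remainders, mirroring the standard log-combining step.
#'
#' @param traces list of \code{posterior_trace} data.frames with
#'   identical parameter sets.
#' @param burnin_fraction fraction of each chain to discard (default 0.10).
#' @return a single combined \code{posterior_trace}.
#' @export
combine_chains <- function(traces, burnin_fraction = 0.10) {
  if (inherits(traces, "data.frame")) traces <- list(traces)
  if (!length(traces)) stop("no traces given")
  cn <- colnames(traces[[1L]])
  for (tr in traces)
    if (!identical(colnames(tr), cn))
      stop("traces have mismatched parameter sets")
  kept <- lapply(traces, function(tr) {
    nb <- floor(burnin_fraction * nrow(tr))
    tr[seq.int(nb + 1L, nrow(tr)), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  for (a in c("tree", "internal_nodes", "merges", "groups", "group_sizes",
              "generation_time", "clock", "prior_only"))
    attr(out, a) <- attr(traces[[1L]], a)
  class(out) <- c("posterior_trace", "data.frame")
  rownames(out) <- NULL
  out
}

#' Effective sample size of an MCMC trace
#'
#' \code{n / (1 + 2 * sum(rho_k))} with the autocorrelation sum truncated
#' by the initial-positive-sequence rule (stop at the first non-positive
#' pair of successive autocorrelations) and the result clipped to
#' \code{[0, n]}. A constant series has no information and reports 0 with
#' a \code{flag} attribute.
#'
#' @param samples numeric vector (>= 10 values).
#' @return effective sample size (numeric scalar).
#' @export
ess <- function(samples) {
  x <- samples[is.finite(samples)]
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (sd(x) == 0) {
    out <- 0
    attr(out, "flag") <- "constant series"
    return(out)
  }
  maxlag <- min(n - 1L, 2000L)
  rho <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1L]
  ssum <- 0
  t <- 1L
  while (t <= length(rho)) {
    pair <- rho[t] + if (t + 1L <= length(rho)) rho[t + 1L] else 0
    if (pair <= 0) break
    ssum <- ssum + pair
    t <- t + 2L
  }
  out <- n / (1 + 2 * ssum)
  min(max(out, 0), n)
}

#' Posterior node-age summary table
#'
#' Per internal node: posterior median age and 95 percent HPD bounds,
#' with branch labels when the tree is annotated.
#'
#' @param trace a (combined) \code{posterior_trace}.
#' @param tree the fixed topology (default: from the trace).
#' @param prob HPD level (default 0.95).
#' @return data.frame with \code{node}, \code{label}, \code{median_age},
#'   \code{hpd_lo}, \code{hpd_hi}, \code{ess}.
#' @export
summarize_node_ages <- function(trace, tree = attr(trace, "tree"),
                                prob = 0.95) {
  cols <- grep("^age_", colnames(trace), value = TRUE)
  nodes <- as.integer(sub("^age_", "", cols))
  n <- length(tree$tip.label)
  labs <- rep(NA_character_, length(nodes))
  if (!is.null(tree$node.label))
    labs <- tree$node.label[nodes - n]
  res <- data.frame(node = nodes, label = labs,
                    median_age = NA_real_, hpd_lo = NA_real_,
                    hpd_hi = NA_real_, ess = NA_real_)
  for (i in seq_along(cols)) {
    x <- trace[[cols[i]]]
    res$median_age[i] <- median(x)
    if (length(unique(x)) == 1L) {
      res$hpd_lo[i] <- res$hpd_hi[i] <- x[1L]
      res$ess[i] <- 0
    } else {
      h <- hpd_interval(x, prob)
      res$hpd_lo[i] <- h[1L]; res$hpd_hi[i] <- h[2L]
      res$ess[i] <- if (length(x) >= 10) ess(x) else NA_real_
    }
  }
  res[order(-res$median_age), ]
}

#' Skyline Ne trajectory from a posterior trace
#'
#' For every posterior state the piecewise-constant \code{Ne(t)} step
#' function implied by the sampled node ages and skyline group sizes is
#' evaluated on a fixed time grid; the pointwise median and HPD envelope
#' are returned. Beyond a state's root age its trajectory is undefined
#' and ignored.
#'
#' @param trace a (combined) \code{posterior_trace} from a skyline run.
#' @param grid time grid in years BP (default: 100 points to the median
#'   root age).
#' @param prob HPD level (default 0.95).
#' @return object of class \code{skyline_trajectory}: data.frame with
#'   \code{time}, \code{median}, \code{lo}, \code{hi}, \code{n_states}.
#' @export
skyline_from_trace <- function(trace, grid = NULL, prob = 0.95) {
  G <- attr(trace, "groups")
  if (is.null(G) || G < 1L) stop("trace has no skyline groups")
  merges <- attr(trace, "merges")
  cols_age <- grep("^age_", colnames(trace), value = TRUE)
  cols_ne <- paste0("Ne_", seq_len(G))
  gs <- attr(trace, "group_sizes")
  nev <- sum(merges)
  ages <- as.matrix(trace[, cols_age, drop = FALSE])
  nem <- as.matrix(trace[, cols_ne, drop = FALSE])
  root_age <- apply(ages, 1L, max)
  if (is.null(grid))
    grid <- seq(0, stats::median(root_age), length.out = 100L)
  bnd_idx <- cumsum(gs)                 # event index closing each group
  S <- nrow(ages)
  vals <- matrix(NA_real_, S, length(grid))
  for (s in seq_len(S)) {
    ev <- sort(rep.int(ages[s, ], merges))
    bnd <- ev[bnd_idx]                  # time upper bound of each group
    gidx <- pmin(findInterval(grid, bnd, left.open = TRUE) + 1L, G)
    ok <- grid <= ev[nev]
    vals[s, ok] <- nem[s, gidx[ok]]
  }
  med <- lo <- hi <- rep(NA_real_, length(grid))
  nst <- integer(length(grid))
  for (j in seq_along(grid)) {
    v <- vals[, j]; v <- v[!is.na(v)]
    nst[j] <- length(v)
    if (length(v) >= 2L) {
      med[j] <- median(v)
      h <- hpd_interval(v, prob)
      lo[j] <- h[1L]; hi[j] <- h[2L]
    }
  }
  structure(data.frame(time = grid, median = med, lo = lo, hi = hi,
                       n_states = nst),
            class = c("skyline_trajectory", "data.frame"))
}
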