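#' Node-calibrated Bayesian dating MCMC with a skyline coalescent prior
#'
#' Samples node ages, the molecular-clock rate and skyline population
#' sizes on a fixed rooted topology. The data enter through per-branch
#' SNP counts: branch \code{b} of duration \code{t_b} contributes
#' \code{Poisson(n_b | r_b * L * t_b)}, with \code{r_b = mu} under the
#' strict clock or \code{mu * m_b} under the relaxed lognormal clock
#' (multipliers with prior mean 1). Node times receive either a Bayesian
#' skyline coalescent prior (piecewise-constant \code{Ne} over
#' \code{skyline_groups} groups of coalescent intervals, log-uniform
#' priors on each \code{Ne}) or a flat prior, plus one or more normal
#' node-age calibrations. \code{mu} has a log-uniform prior within
#' \code{mu_bounds}.
#'
#' Proposals: bounded uniform slides on internal node ages, scale moves
#' on the root height, \code{mu}, each \code{Ne}, the relaxed multipliers
#' and their stdev, and a joint up/down scale of all ages against
#' \code{mu}. With all SNP counts zero the sampler runs prior-only.
#'
#' @param tree rooted \code{phylo} (fixed topology; branch lengths, if
#'   present and ultrametric, seed the initial ages).
#' @param snp_counts SNP counts per branch, aligned with
#'   \code{tree$edge} rows (see \code{\link{snp_counts_from_assignment}}).
#' @param L callable length in bases.
#' @param calibration list \code{list(node, mean, sd)} (years BP), or a
#'   list of such lists.
#' @param clock \code{"strict"} or \code{"relaxed"} (lognormal).
#' @param tree_prior \code{"skyline"} or \code{"flat"}.
#' @param skyline_groups number of skyline groups (default 5).
#' @param generation_time years per generation (default 31).
#' @param chains number of independent chains (default 2).
#' @param n_sweeps full parameter sweeps per chain (default 2000).
#' @param thin record every \code{thin}-th sweep (default 2).
#' @param seed integer seed; chain \code{i} uses a seed derived from it.
#' @param mu_bounds,Ne_bounds log-uniform prior supports.
#' @param relaxed_s_mean exponential prior mean of the lognormal stdev.
#' @param steps half-widths of the log-scale proposal windows.
#' @param n_updown joint up/down proposals per sweep; this move traverses
#'   the likelihood-flat rate-time ridge and dominates mixing of the
#'   root age and clock rate.
#' @return list of \code{posterior_trace} data.frames (one per chain)
#'   with columns \code{state}, \code{logpost}, \code{loglik}, \code{mu},
#'   \code{cov}, \code{s}, \code{Ne_*}, \code{age_<node>}.
#' @export
run_dating_mcmc <- function(tree, snp_counts, L, calibration,
                            clock = c("strict", "relaxed"),
                            tree_prior = c("skyline", "flat"),
                            skyline_groups = 5, generation_time = 31,
                            chains = 2, n_sweeps = 2000, thin = 2,
                            seed = 1L,
                            mu_bounds = c(1e-11, 1e-8),
                            Ne_bounds = c(1, 1e8),
                            relaxed_s_mean = 0.3,
                            steps = list(root = 0.25, mu = 0.4,
                                         updown = 0.15, Ne = 0.6,
                                         mult = 0.3, s = 0.3),
                            n_updown = 5L) {
  clock <- match.arg(clock)
  tree_prior <- match.arg(tree_prior)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  edge <- tree$edge
  E <- nrow(edge)
  pa <- edge[, 1L]; chn <- edge[, 2L]
  if (length(snp_counts) != E)
    stop("snp_counts must align with tree$edge rows")
  nb <- as.numeric(snp_counts)
  prior_only <- all(nb == 0)
  if (is.null(calibration)) stop("a node-age calibration is required")
  if (!is.null(calibration$node)) calibration <- list(calibration)
  for (cal in calibration) {
    if (cal$node < n + 1L || cal$node > nn)
      stop("calibration node ", cal$node, " absent from tree")
    if (cal$sd <= 0) stop("calibration sd must be positive")
  }
  ch <- children_list(tree)
  internal <- (n + 1L):nn
  merges <- lengths(ch[internal]) - 1L   # polytomy = simultaneous merges
  nev <- sum(merges)
  if (tree_prior == "skyline" && skyline_groups > nev)
    stop("skyline_groups exceeds the number of coalescent events")
  G <- if (tree_prior == "skyline") as.integer(skyline_groups) else 0L
  grp_sizes <- if (G > 0) {
    b <- diff(round(seq(0, nev, length.out = G + 1)))
    if (any(b < 1)) b <- rep(nev %/% G, G) + c(rep(1, nev %% G),
                                               rep(0, G - nev %% G))
    as.integer(b)
  } else integer(0)
  ev_group <- if (G > 0) rep(seq_len(G), grp_sizes) else integer(0)
  g <- generation_time

  # initial ages: from branch lengths when usable, else topological ladder
  init_ages <- function() {
    a <- tryCatch({
      if (is.null(tree$edge.length)) stop("no lengths")
      aa <- node_ages(tree)
      if (any(aa[pa] - aa[chn] <= 0)) stop("not ultrametric")
      aa
    }, error = function(e) {
      h <- numeric(nn)
      eo <- ape::reorder.phylo(tree, "postorder")$edge
      for (j in seq_len(nrow(eo)))
        h[eo[j, 1L]] <- max(h[eo[j, 1L]], h[eo[j, 2L]] + 1)
      h
    })
    cal1 <- calibration[[1L]]
    if (a[cal1$node] > 0) a <- a * (cal1$mean / a[cal1$node])
    a[seq_len(n)] <- 0
    a
  }

  cc_ev <- {kk <- n - seq_len(nev) + 1; kk * (kk - 1) / 2}
  rt_node <- root_node(tree)
  cal_nodes <- vapply(calibration, `[[`, 1, "node")
  cal_means <- vapply(calibration, `[[`, 1, "mean")
  cal_sds <- vapply(calibration, `[[`, 1, "sd")
  sum_nb <- sum(nb)
  all_single <- all(merges == 1L)
  # log-posterior up to additive constants; returns c(lp, loglik)
  mk_logpost <- function() {
    function(ages, mu, lmult, s, Ne) {
      tb <- ages[pa] - ages[chn]
      if (any(tb <= 0)) return(c(-Inf, NA_real_))
      ll <- 0
      if (!prior_only) {
        muL <- mu * L
        if (is.null(lmult)) {
          ll <- sum(nb * log(tb)) + sum_nb * log(muL) - muL * sum(tb)
        } else {
          ll <- sum(nb * (log(tb) + lmult)) + sum_nb * log(muL) -
            muL * sum(exp(lmult) * tb)
        }
      }
      lp <- ll
      if (G > 0) {
        if (any(Ne < Ne_bounds[1] | Ne > Ne_bounds[2]))
          return(c(-Inf, ll))
        ev <- if (all_single) sort.int(ages[internal], method = "quick")
              else sort.int(rep.int(ages[internal], merges),
                            method = "quick")
        dt <- ev - c(0, ev[-nev])
        lNe <- log(Ne)
        lp <- lp - sum(cc_ev * dt / (2 * g * Ne[ev_group])) -
          sum(grp_sizes * lNe) - sum(lNe)
      } else {
        # flat tree prior in the node-height ratio parameterization:
        # conditional on the root age, internal configurations are
        # uniform, so a root calibration is reproduced exactly under
        # prior-only sampling
        lp <- lp - (length(internal) - 1L) * log(ages[rt_node])
      }
      lp <- lp - 0.5 * sum(((ages[cal_nodes] - cal_means) / cal_sds)^2)
      if (mu < mu_bounds[1] || mu > mu_bounds[2]) return(c(-Inf, ll))
      lp <- lp - log(mu)
      if (clock == "relaxed") {
        if (s <= 0) return(c(-Inf, ll))
        lp <- lp - 0.5 * sum(((lmult + s^2 / 2) / s)^2) - E * log(s) -
          s / relaxed_s_mean
      }
      c(lp, ll)
    }
  }
  logpost <- mk_logpost()

  run_chain <- function(chain_seed) {
    set.seed(.yc_check_seed(chain_seed))
    ages <- init_ages()
    mu <- if (prior_only) sqrt(prod(mu_bounds)) else {
      tt <- sum(ages[pa] - ages[chn])
      min(max(sum(nb) / (L * tt), mu_bounds[1] * 2), mu_bounds[2] / 2)
    }
    lmult <- if (clock == "relaxed") numeric(E) else NULL
    s <- relaxed_s_mean / 3
    Ne <- rep(max(Ne_bounds[1] * 10,
                  min(ages[root_node(tree)] / (2 * g), Ne_bounds[2] / 10)),
              max(G, 1L))[seq_len(max(G, 0L))]
    cur <- logpost(ages, mu, lmult, s, Ne)
    if (!is.finite(cur[1])) stop("invalid MCMC initialization")
    nrec <- floor(n_sweeps / thin)
    nage <- length(internal)
    out <- matrix(NA_real_, nrec,
                  5L + G + nage)
    colnames(out) <- c("state", "logpost", "loglik", "mu", "cov",
                       if (G > 0) paste0("Ne_", seq_len(G)),
                       paste0("age_", internal))
    if (clock == "relaxed") {
      out <- cbind(out, s = NA_real_)
    }
    rt <- root_node(tree)
    non_root <- setdiff(internal, rt)
    pv <- parent_vec(tree)
    rec <- 0L
    for (sw in seq_len(n_sweeps)) {
      # node-age slides (bounded uniform, symmetric)
      for (v in sample(non_root)) {
        lo <- max(ages[ch[[v]]])
        hi <- ages[pv[v]]
        a2 <- ages; a2[v] <- runif(1, lo, hi)
        prop <- logpost(a2, mu, lmult, s, Ne)
        if (log(runif(1)) < prop[1] - cur[1]) { ages <- a2; cur <- prop }
      }
      # root-height scale
      cc <- exp(runif(1, -steps$root, steps$root))
      a2 <- ages; a2[rt] <- ages[rt] * cc
      prop <- logpost(a2, mu, lmult, s, Ne)
      if (log(runif(1)) < prop[1] - cur[1] + log(cc)) {
        ages <- a2; cur <- prop
      }
      # clock-rate scale
      cc <- exp(runif(1, -steps$mu, steps$mu))
      prop <- logpost(ages, mu * cc, lmult, s, Ne)
      if (log(runif(1)) < prop[1] - cur[1] + log(cc)) {
        mu <- mu * cc; cur <- prop
      }
      # joint up/down: all ages up, mu down (likelihood-invariant ridge)
      for (k in seq_len(n_updown)) {
        cc <- exp(runif(1, -steps$updown, steps$updown))
        a2 <- ages; a2[internal] <- ages[internal] * cc
        prop <- logpost(a2, mu / cc, lmult, s, Ne)
        if (log(runif(1)) < prop[1] - cur[1] + (nage - 1) * log(cc)) {
          ages <- a2; mu <- mu / cc; cur <- prop
        }
      }
      # skyline sizes
      if (G > 0) for (j in seq_len(G)) {
        cc <- exp(runif(1, -steps$Ne, steps$Ne))
        Ne2 <- Ne; Ne2[j] <- Ne[j] * cc
        prop <- logpost(ages, mu, lmult, s, Ne2)
        if (log(runif(1)) < prop[1] - cur[1] + log(cc)) {
          Ne <- Ne2; cur <- prop
        }
      }
      # relaxed-clock multipliers and their spread
      if (clock == "relaxed") {
        for (e in sample(E)) {
          l2 <- lmult; l2[e] <- lmult[e] + runif(1, -steps$mult, steps$mult)
          prop <- logpost(ages, mu, l2, s, Ne)
          if (log(runif(1)) < prop[1] - cur[1]) { lmult <- l2; cur <- prop }
        }
        cc <- exp(runif(1, -steps$s, steps$s))
        prop <- logpost(ages, mu, lmult, s * cc, Ne)
        if (log(runif(1)) < prop[1] - cur[1] + log(cc)) {
          s <- s * cc; cur <- prop
        }
      }
      if (sw %% thin == 0L) {
        rec <- rec + 1L
        cov <- if (clock == "relaxed") {
          rates <- mu * exp(lmult)
          sd(rates) / mean(rates)
        } else 0
        row <- c(sw, cur[1], cur[2], mu, cov,
                 if (G > 0) Ne, ages[internal])
        if (clock == "relaxed") row <- c(row, s)
        out[rec, ] <- row
      }
    }
    tr <- as.data.frame(out[seq_len(rec), , drop = FALSE])
    attr(tr, "tree") <- tree
    attr(tr, "internal_nodes") <- internal
    attr(tr, "merges") <- merges
    attr(tr, "groups") <- G
    attr(tr, "group_sizes") <- grp_sizes
    attr(tr, "generation_time") <- g
    attr(tr, "clock") <- clock
    attr(tr, "prior_only") <- prior_only
    class(tr) <- c("posterior_trace", "data.frame")
    tr
  }

  base <- .yc_check_seed(seed)
  lapply(seq_len(chains), function(i)
    run_chain((base + (i - 1) * 1000003) %% .Machine$integer.max))
}
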