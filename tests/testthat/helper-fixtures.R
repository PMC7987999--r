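# shared fixture builders and independent oracles

# scale a dated tree so the root sits at `target` years BP
rescale_root <- function(tree, target) {
  a <- max(node_ages(tree))
  tree$edge.length <- tree$edge.length * target / a
  tree
}

# simulated cohort with tiled mask, de-clustered singleton runs and
# injected QC artifacts; ground truth for every artifact class
qc_fixture <- function(n_samples = 60, Ne = 3000, L = 8e6, seed = 1,
                       spec = list(singleton_clusters = 5,
                                   replicate_discordances = 2,
                                   recurrent_sites = 3,
                                   missing_blocks = 2)) {
  tree <- simulate_genealogy(n_samples, demography_model(Ne), seed = seed)
  sim <- drop_mutations(tree, 7e-10, L, seed = seed + 1)
  sim$matrix$mask <- tiled_mask(L)
  sim <- respace_singleton_runs(sim, seed = seed + 2)
  inj <- inject_qc_artifacts(sim$matrix, tree, spec = spec, seed = seed + 3)
  groups <- lapply(inj$truth$replicate_discordances, `[[`, "group")
  list(tree = tree, clean = sim, inj = inj, groups = groups, L = L)
}

# positions of all labelled artifact sites of a fixture
artifact_positions <- function(truth) {
  c(unlist(lapply(truth$singleton_clusters, `[[`, "positions")),
    unlist(lapply(truth$replicate_discordances, `[[`, "positions")),
    vapply(truth$recurrent_sites, `[[`, numeric(1), "pos"),
    unlist(lapply(truth$missing_blocks, `[[`, "positions")))
}

# 0-based half-open regions of all labelled artifacts (single-base
# regions for site-level artifacts)
artifact_regions <- function(truth) {
  site_pos <- c(unlist(lapply(truth$replicate_discordances, `[[`,
                              "positions")),
                vapply(truth$recurrent_sites, `[[`, numeric(1), "pos"))
  rbind(do.call(rbind, lapply(truth$singleton_clusters, `[[`, "region")),
        do.call(rbind, lapply(truth$missing_blocks, `[[`, "region")),
        cbind(site_pos - 1, site_pos))
}

# exhaustive small-parsimony oracle: minimum state changes of a binary
# site over all internal-state assignments (missing tips are free)
brute_force_changes <- function(tree, states) {
  n <- length(tree$tip.label)
  states <- states[tree$tip.label]
  free_tips <- which(is.na(states))
  nin <- tree$Nnode
  stopifnot(nin + length(free_tips) <= 16)
  best <- Inf
  combos <- expand.grid(rep(list(0:1), nin + length(free_tips)))
  full <- numeric(n + nin)
  full[seq_len(n)] <- states
  for (r in seq_len(nrow(combos))) {
    full[(n + 1):(n + nin)] <- as.numeric(combos[r, seq_len(nin)])
    if (length(free_tips))
      full[free_tips] <- as.numeric(combos[r, nin + seq_along(free_tips)])
    ch <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# the topology that SNP data can determine: the truth genealogy with
# internal branches carrying zero mutations collapsed into polytomies
collapse_unsupported <- function(tree, truth) {
  counts <- tabulate(truth$branch, nbins = length(tree$tip.label) +
                       tree$Nnode)
  t2 <- tree
  internal_child <- t2$edge[, 2L] > length(t2$tip.label)
  t2$edge.length[internal_child & counts[t2$edge[, 2L]] == 0L] <- 0
  ape::di2multi(t2, tol = 1e-12)
}

# dated two-tip tree with equal branch lengths
two_tip_tree <- function(t = 1000) {
  ape::read.tree(text = sprintf("(A:%f,B:%f);", t, t))
}
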