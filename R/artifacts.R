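#' Respace natural singleton runs in a simulated matrix
#'
#' Uniformly drawn mutation positions occasionally place two singletons
#' of the same carrier within the cluster window by chance; on real data
#' such runs are indistinguishable from the terminal-branch artifacts the
#' QC removes. For fixtures with unambiguous ground truth this helper
#' re-draws the offending positions (keeping carriers, hence the perfect
#' phylogeny, intact) until no natural same-carrier run remains --
#' i.e. it conditions the uniform position draw on the no-cluster event.
#'
#' @param sim a \code{\link{drop_mutations}} result (list with
#'   \code{matrix} and \code{truth}).
#' @param window the QC cluster window in bp (default 50).
#' @param seed integer seed.
#' @return the modified \code{sim} list.
#' @export
respace_singleton_runs <- function(sim, window = 50, seed = 1L) {
  set.seed(.yc_check_seed(seed))
  gm <- sim$matrix
  truth <- sim$truth
  L <- max(gm$mask$end)
  repeat {
    der <- rowSums(gm$geno == 1L, na.rm = TRUE)
    singles <- which(der == 1L)
    carrier <- vapply(singles, function(i) which(gm$geno[i, ] == 1L)[1L], 1L)
    move <- integer(0)
    for (grp in split(singles, carrier)) {
      if (length(grp) < 2L) next
      p <- gm$pos[grp]
      runid <- cumsum(c(1, diff(p) > window))
      for (r in split(grp, runid))
        if (length(r) >= 2L) move <- c(move, r[-1L])
    }
    if (!length(move)) break
    for (i in move) {
      repeat {
        cand <- sample.int(L, 1L)
        if (!any(abs(gm$pos - cand) <= window)) break
      }
      oldpos <- gm$pos[i]
      gm$pos[i] <- cand
      truth$pos[truth$pos == oldpos] <- cand
    }
    o <- order(gm$pos)
    gm$geno <- gm$geno[o, , drop = FALSE]
    gm$pos <- gm$pos[o]
    truth <- truth[order(truth$pos), , drop = FALSE]
  }
  sim$matrix <- gm
  sim$truth <- truth
  sim
}

#' Inject labelled QC artifacts into a clean genotype matrix
#'
#' Plants the four artifact classes that the region-based QC rules are
#' designed to remove, at positions chosen to keep ground truth
#' unambiguous (no two injections overlap, and injected regions avoid
#' pre-existing sites):
#' \itemize{
#'   \item \code{singleton_clusters}: runs of >= 2 same-carrier singletons
#'     with successive gaps <= \code{window} bp;
#'   \item \code{replicate_discordances}: a duplicated sample column
#'     (suffix \code{_rep}) discordant with its source at labelled sites;
#'   \item \code{recurrent_sites}: sites whose carrier set is the union of
#'     three disjoint clades, hence needing >= 3 origins on the truth tree;
#'   \item \code{missing_blocks}: short runs of sites with > 10 percent
#'     no-calls and no clean variant between them.
#' }
#'
#' @param gm a \code{\link{geno_matrix}} (clean, homoplasy-free).
#' @param tree the truth genealogy the matrix was simulated on.
#' @param spec named list of artifact counts (see Details); classes absent
#'   from the list default to 0.
#' @param seed integer seed.
#' @param window singleton-cluster gap bound in bp (default 50).
#' @return list with \code{matrix} (the contaminated
#'   \code{\link{geno_matrix}}) and \code{truth}, a list recording every
#'   injected feature (class \code{artifact_truth}).
#' @export
inject_qc_artifacts <- function(gm, tree,
                                spec = list(), seed = 1L, window = 50) {
  known <- c("singleton_clusters", "replicate_discordances",
             "recurrent_sites", "missing_blocks")
  if (length(spec) && !all(names(spec) %in% known))
    stop("unknown artifact class: ",
         paste(setdiff(names(spec), known), collapse = ", "))
  cnt <- setNames(rep(0L, length(known)), known)
  cnt[names(spec)] <- vapply(spec, as.integer, 1L)
  set.seed(.yc_check_seed(seed))
  L <- max(gm$mask$end)
  occupied <- sort(gm$pos)
  reserved_lo <- numeric(0); reserved_hi <- numeric(0)

  claim_window <- function(width, guard) {
    for (try in seq_len(500L)) {
      a <- sample.int(L - width - 2L * guard, 1L) + guard
      b <- a + width
      if (any(occupied >= a - guard & occupied <= b + guard)) next
      if (any(pmax(reserved_lo, a - guard) <= pmin(reserved_hi, b + guard)))
        next
      reserved_lo <<- c(reserved_lo, a - guard)
      reserved_hi <<- c(reserved_hi, b + guard)
      return(c(a, b))
    }
    stop("could not place artifact without overlapping injections")
  }

  truth <- list(singleton_clusters = list(), replicate_discordances = list(),
                recurrent_sites = list(), missing_blocks = list())
  new_pos <- numeric(0); new_rows <- list()
  nsamp <- length(gm$samples)
  tu <- tips_under(tree)
  add_site <- function(pos, carriers_idx, na_idx = integer(0)) {
    row <- rep(0L, nsamp)
    row[carriers_idx] <- 1L
    row[na_idx] <- NA_integer_
    new_pos <<- c(new_pos, pos)
    new_rows[[length(new_rows) + 1L]] <<- row
  }

  # --- singleton clusters -------------------------------------------------
  for (i in seq_len(cnt["singleton_clusters"])) {
    k <- sample(2:3, 1L)
    gaps <- sample(10:window, k - 1L, replace = TRUE)
    w <- claim_window(sum(gaps), guard = window + 10)
    ps <- w[1] + c(0, cumsum(gaps))
    carrier <- sample.int(nsamp, 1L)
    for (p in ps) add_site(p, carrier)
    truth$singleton_clusters[[i]] <-
      list(sample = gm$samples[carrier], positions = ps,
           region = c(min(ps) - 1 - window, max(ps) + window))
  }

  # --- recurrent sites ----------------------------------------------------
  nt <- length(tree$tip.label)
  clade_nodes <- which(lengths(tu) >= 2 & lengths(tu) <= max(2, nt %/% 3))
  clade_nodes <- setdiff(clade_nodes, root_node(tree))
  for (i in seq_len(cnt["recurrent_sites"])) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      br <- sample(clade_nodes, 3L)
      tipsets <- tu[br]
      if (length(unique(unlist(tipsets))) != sum(lengths(tipsets))) next
      carriers <- sort(unlist(tipsets))
      states <- rep(0L, nt); states[carriers] <- 1L
      names(states) <- tree$tip.label
      if (fitch_changes(tree, t(as.matrix(states)))[1] < 3L) next
      w <- claim_window(1, guard = window + 10)
      idx <- match(tree$tip.label[carriers], gm$samples)
      add_site(w[1], idx)
      truth$recurrent_sites[[i]] <-
        list(pos = w[1], branches = br, n_origins = 3L)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not construct a 3-origin recurrent site")
  }

  # --- missing blocks -----------------------------------------------------
  for (i in seq_len(cnt["missing_blocks"])) {
    spacing <- c(300, 300)
    w <- claim_window(sum(spacing), guard = 120)
    ps <- w[1] + c(0, cumsum(spacing))
    node <- sample(clade_nodes, 1L)
    carriers <- match(tree$tip.label[tu[[node]]], gm$samples)
    n_na <- ceiling(0.15 * nsamp)
    napos <- list()
    for (p in ps) {
      na_idx <- sample(setdiff(seq_len(nsamp), carriers), n_na)
      add_site(p, carriers, na_idx)
      napos[[as.character(p)]] <- na_idx
    }
    truth$missing_blocks[[i]] <-
      list(positions = ps, region = c(min(ps) - 1, max(ps)), branch = node)
  }

  # assemble the site-extended matrix before duplicating columns
  geno <- gm$geno
  if (length(new_rows)) {
    geno <- rbind(geno, do.call(rbind, new_rows))
    pos <- c(gm$pos, new_pos)
    o <- order(pos)
    geno <- geno[o, , drop = FALSE]
    pos <- pos[o]
  } else pos <- gm$pos

  # --- replicate discordances --------------------------------------------
  platform <- gm$platform
  samples <- gm$samples
  for (i in seq_len(cnt["replicate_discordances"])) {
    used <- unlist(lapply(truth$replicate_discordances, `[[`, "group"))
    src <- sample(setdiff(samples, used), 1L)
    copy <- paste0(src, "_rep")
    geno <- cbind(geno, geno[, src])
    colnames(geno)[ncol(geno)] <- copy
    dps <- vapply(1:2, function(d) claim_window(1, guard = window + 10)[1],
                  numeric(1))
    for (d in dps) {                     # derived only in the copy
      row <- rep(0L, ncol(geno)); row[ncol(geno)] <- 1L
      geno <- rbind(geno, row)
      pos <- c(pos, d)
    }
    o <- order(pos)
    geno <- geno[o, , drop = FALSE]; pos <- pos[o]
    samples <- c(samples, copy)
    platform <- c(platform, setNames(platform[src], copy))
    truth$replicate_discordances[[i]] <-
      list(group = c(src, copy), positions = sort(dps))
  }

  out <- geno_matrix(geno, pos, samples = samples, platform = platform,
                     mask = gm$mask)
  structure(list(matrix = out, truth = structure(truth,
                                                 class = "artifact_truth")),
            names = c("matrix", "truth"))
}
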