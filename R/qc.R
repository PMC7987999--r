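#' Restrict a call set to a callable-region mask
#'
#' First step of the QC pipeline: retains exactly the sites whose 1-based
#' position lies inside the (0-based half-open) mask and attaches the mask
#' to the matrix.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param mask a \code{\link{region_mask}}; unsorted or overlapping
#'   intervals are rejected by the mask constructor.
#' @return the filtered \code{geno_matrix} with \code{mask} set.
#' @export
apply_region_mask <- function(gm, mask) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!inherits(mask, "region_mask"))
    mask <- region_mask(mask$start, mask$end)
  keep <- pos_in_mask(gm$pos, mask)
  gm <- gm_subset_sites(gm, keep)
  gm$mask <- mask
  gm
}

#' Exclude same-carrier singleton clusters
#'
#' Terminal-branch artifact rule: a run of two or more singletons (sites
#' whose derived allele occurs in exactly one sample) carried by the
#' \emph{same} sample, with successive gaps <= \code{window} bp, marks an
#' unreliable region. The excluded region spans the run extended by
#' \code{window} bp on each side; every site inside it is dropped and the
#' mask is updated.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param window gap and extension bound in bp (default 50).
#' @param same_carrier if \code{FALSE}, cluster singletons regardless of
#'   carrier.
#' @return list: \code{matrix}, \code{excluded} (a \code{region_mask} of
#'   excised regions), \code{clusters} (per-cluster carrier/positions).
#' @export
filter_singleton_clusters <- function(gm, window = 50, same_carrier = TRUE) {
  der <- rowSums(gm$geno == 1L, na.rm = TRUE)
  singles <- which(der == 1L)
  carrier <- rep(NA_integer_, length(gm$pos))
  for (i in singles) carrier[i] <- which(gm$geno[i, ] == 1L)
  ex_lo <- numeric(0); ex_hi <- numeric(0); clusters <- list()
  groups <- if (same_carrier) split(singles, carrier[singles])
            else list(all = singles)
  for (grp in groups) {
    if (length(grp) < 2L) next
    p <- sort(gm$pos[grp])
    runid <- cumsum(c(1, diff(p) > window))
    for (r in split(p, runid)) {
      if (length(r) < 2L) next
      ex_lo <- c(ex_lo, max(0, min(r) - 1 - window))
      ex_hi <- c(ex_hi, max(r) + window)
      clusters[[length(clusters) + 1L]] <-
        list(carrier = gm$samples[carrier[grp[1L]]], positions = r)
    }
  }
  excl <- if (length(ex_lo)) {
    o <- order(ex_lo)
    from_iranges(as_iranges(list(start = ex_lo[o], end = ex_hi[o])))
  } else region_mask()
  keep <- !pos_in_mask(gm$pos, excl)
  gm <- gm_subset_sites(gm, keep)
  gm$mask <- mask_subtract(gm$mask, excl)
  list(matrix = gm, excluded = excl, clusters = clusters)
}

#' Resolve replicate/paternally-related sample groups
#'
#' For every group of columns known to be the same (or paternally
#' related) individual: any site at which two group members carry
#' discordant non-missing calls invalidates its whole containing
#' callable-mask interval; afterwards exactly one column per group is
#' retained -- the one with the fewest no-calls, ties broken by sample ID
#' order.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param groups list of character vectors of sample names.
#' @return list: \code{matrix}, \code{excluded} regions, \code{kept}
#'   (named character: kept column per group), \code{discordant_pos}.
#' @export
filter_replicate_discordance <- function(gm, groups) {
  if (length(groups) == 0L)
    return(list(matrix = gm, excluded = region_mask(),
                kept = character(0), discordant_pos = numeric(0)))
  unknown <- setdiff(unlist(groups), gm$samples)
  if (length(unknown))
    stop("replicate group references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  disc <- logical(length(gm$pos))
  kept <- character(length(groups))
  drop <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    sub <- gm$geno[, g, drop = FALSE]
    for (a in seq_len(length(g) - 1L)) for (b in seq((a + 1L), length(g))) {
      cmp <- !is.na(sub[, a]) & !is.na(sub[, b]) & sub[, a] != sub[, b]
      disc <- disc | cmp
    }
    ncalls <- colSums(is.na(sub))
    best <- g[order(ncalls, g)][1L]
    kept[gi] <- best
    drop <- c(drop, setdiff(g, best))
  }
  iv <- mask_interval_of(gm$pos[disc], gm$mask)
  iv <- sort(unique(iv[!is.na(iv)]))
  excl <- if (length(iv)) region_mask(gm$mask$start[iv], gm$mask$end[iv])
          else region_mask()
  dpos <- gm$pos[disc]
  gm <- gm_drop_samples(gm, drop)
  keep_site <- !pos_in_mask(gm$pos, excl) &
    rowSums(gm$geno == 1L, na.rm = TRUE) > 0L
  gm <- gm_subset_sites(gm, keep_site)
  gm$mask <- mask_subtract(gm$mask, excl)
  names(kept) <- vapply(groups, paste, "", collapse = "+")
  list(matrix = gm, excluded = excl, kept = kept, discordant_pos = dpos)
}

#' Exclude regions with platform-recurrent sites
#'
#' Within each sequencing-platform subset of samples, every site's minimum
#' number of state changes on the preliminary tree is scored by small
#' parsimony. Sites needing \code{min_branches} or more independent
#' origins in any platform subset condemn their containing callable-mask
#' interval; sites needing exactly two origins are retained but flagged
#' recurrent.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param prelim_tree rooted tree spanning (at least) the matrix samples.
#' @param min_branches exclusion threshold on origin count (default 3).
#' @param platform per-sample platform labels (default: from \code{gm}).
#' @return list: \code{matrix}, \code{excluded} regions,
#'   \code{flagged_pos} (2-origin sites kept), \code{max_changes}.
#' @export
filter_recurrent_site_regions <- function(gm, prelim_tree, min_branches = 3,
                                          platform = NULL) {
  if (is.null(platform)) platform <- gm$platform
  if (!all(gm$samples %in% prelim_tree$tip.label))
    stop("preliminary tree does not span all matrix samples")
  mx <- integer(length(gm$pos))
  for (pf in unique(platform[gm$samples])) {
    ss <- gm$samples[platform[gm$samples] == pf]
    if (length(ss) < 3L) next
    tr <- ape::keep.tip(prelim_tree, ss)
    ch <- fitch_changes(tr, gm$geno[, ss, drop = FALSE])
    mx <- pmax(mx, ch)
  }
  bad <- mx >= min_branches
  iv <- mask_interval_of(gm$pos[bad], gm$mask)
  iv <- sort(unique(iv[!is.na(iv)]))
  excl <- if (length(iv)) region_mask(gm$mask$start[iv], gm$mask$end[iv])
          else region_mask()
  flagged <- gm$pos[mx == (min_branches - 1L) & !bad]
  keep <- !pos_in_mask(gm$pos, excl)
  flags <- (mx == (min_branches - 1L))[keep]
  gm <- gm_subset_sites(gm, keep)
  gm$mask <- mask_subtract(gm$mask, excl)
  list(matrix = gm, excluded = excl, flagged_pos = flagged,
       recurrent_flag = flags)
}

#' Exclude high-missingness sites and barren inter-site gaps
#'
#' Sites with a no-call fraction strictly above \code{max_missing} are
#' dropped and their single-base positions removed from the mask. In
#' addition, the gap between two consecutive such marked positions is
#' excluded when it contains no retained variant and its length is at
#' most \code{proximity} bp.
#'
#' @param gm a \code{\link{geno_matrix}}.
#' @param max_missing missingness threshold (default 0.10, strict).
#' @param proximity inter-site gap bound in bp (default 1000).
#' @return list: \code{matrix}, \code{excluded} regions,
#'   \code{marked_pos}.
#' @export
filter_missingness <- function(gm, max_missing = 0.10, proximity = 1000) {
  frac <- rowMeans(is.na(gm$geno))
  bad <- frac > max_missing
  marked <- sort(unique(gm$pos[bad]))
  keep_pos <- gm$pos[!bad]
  ex_lo <- numeric(0); ex_hi <- numeric(0)
  if (length(marked)) {
    ex_lo <- marked - 1; ex_hi <- marked      # the marked bases themselves
    if (length(marked) > 1L) {
      for (i in seq_len(length(marked) - 1L)) {
        p1 <- marked[i]; p2 <- marked[i + 1L]
        if (p2 - p1 <= proximity &&
            !any(keep_pos > p1 & keep_pos < p2)) {
          ex_lo <- c(ex_lo, p1 - 1); ex_hi <- c(ex_hi, p2)
        }
      }
    }
  }
  excl <- if (length(ex_lo)) {
    o <- order(ex_lo)
    from_iranges(as_iranges(list(start = ex_lo[o], end = ex_hi[o])))
  } else region_mask()
  gm <- gm_subset_sites(gm, !bad)
  gm$mask <- mask_subtract(gm$mask, excl)
  list(matrix = gm, excluded = excl, marked_pos = marked)
}

#' Run the full region-based QC pipeline
#'
#' Applies, in fixed order: callable-region mask, replicate-discordance
#' resolution, singleton-cluster exclusion, platform-recurrence exclusion
#' (on a preliminary perfect-phylogeny tree built from the current
#' matrix), and missingness filtering. A site removable by several rules
#' is attributed to the first rule that sees it.
#'
#' @param gm a \code{\link{geno_matrix}} of raw calls.
#' @param mask callable \code{\link{region_mask}}.
#' @param replicate_groups list of same-individual sample-name groups.
#' @param outgroup optional outgroup sample for the preliminary tree.
#' @param window,min_branches,max_missing,proximity rule parameters.
#' @return list: \code{matrix} (final calls), \code{mask} (final mask),
#'   \code{report} (a \code{filter_report}), \code{prelim_tree}.
#' @export
run_qc <- function(gm, mask = gm$mask, replicate_groups = list(),
                   outgroup = NULL, window = 50, min_branches = 3,
                   max_missing = 0.10, proximity = 1000) {
  n0 <- length(gm$pos)
  len0 <- callable_length(mask)
  gm <- apply_region_mask(gm, mask)
  n_mask <- n0 - length(gm$pos)

  st_rep <- filter_replicate_discordance(gm, replicate_groups)
  n_rep <- length(gm$pos) - length(st_rep$matrix$pos)
  gm <- st_rep$matrix

  st_sg <- filter_singleton_clusters(gm, window = window)
  n_sg <- length(gm$pos) - length(st_sg$matrix$pos)
  gm <- st_sg$matrix

  prelim <- build_parsimony_tree(gm, outgroup = outgroup)
  st_rc <- filter_recurrent_site_regions(gm, prelim,
                                         min_branches = min_branches)
  n_rc <- length(gm$pos) - length(st_rc$matrix$pos)
  gm <- st_rc$matrix

  st_ms <- filter_missingness(gm, max_missing = max_missing,
                              proximity = proximity)
  n_ms <- length(gm$pos) - length(st_ms$matrix$pos)
  gm <- st_ms$matrix

  report <- structure(list(
    input_sites = n0,
    excluded = c(region_mask = n_mask, replicate_discordance = n_rep,
                 singleton_cluster = n_sg, recurrent_region = n_rc,
                 missingness = n_ms),
    surviving_sites = length(gm$pos),
    callable_before = len0,
    callable_after = callable_length(gm$mask),
    replicate_kept = st_rep$kept,
    flagged_recurrent = st_rc$flagged_pos,
    excluded_regions = list(replicate_discordance = st_rep$excluded,
                            singleton_cluster = st_sg$excluded,
                            recurrent_region = st_rc$excluded,
                            missingness = st_ms$excluded)),
    class = "filter_report")
  list(matrix = gm, mask = gm$mask, report = report, prelim_tree = prelim)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter report\n")
  cat("  input sites:     ", x$input_sites, "\n")
  for (nm in names(x$excluded))
    cat(sprintf("  - %-22s %d excluded\n", nm, x$excluded[[nm]]))
  cat("  surviving sites: ", x$surviving_sites, "\n")
  cat(sprintf("  callable length: %s -> %s bases\n",
              format(x$callable_before, big.mark = ","),
              format(x$callable_after, big.mark = ",")))
  invisible(x)
}
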