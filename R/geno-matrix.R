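#' Region mask on chromosome Y
#'
#' A set of callable intervals in BED convention: 0-based, half-open
#' \code{[start, end)}, sorted and non-overlapping. A 1-based variant
#' position \code{POS} lies inside interval \code{(start, end)} iff
#' \code{start < POS <= end}.
#'
#' @param start,end integer vectors of interval bounds (0-based half-open).
#' @return an object of class \code{region_mask}.
#' @export
region_mask <- function(start = integer(0), end = integer(0)) {
  if (length(start) != length(end)) stop("start/end length mismatch")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("mask intervals must satisfy start < end")
  if (is.unsorted(start, strictly = TRUE) && length(start) > 1)
    stop("mask intervals must be sorted")
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("mask intervals must be non-overlapping")
  structure(list(start = start, end = end), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("region_mask:", length(x$start), "interval(s),",
      format(callable_length(x), big.mark = ","), "callable bases\n")
  invisible(x)
}

#' Total callable length of a mask
#'
#' @param mask a \code{\link{region_mask}}.
#' @return sum of interval widths in bases.
#' @export
callable_length <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  sum(mask$end - mask$start)
}

#' Regular tiling of a callable region
#'
#' A mask of consecutive \code{tile}-sized intervals covering
#' \code{[0, L)}. Real callable masks are fragmented into thousands of
#' intervals; rules that excise a "containing callable interval" need
#' that granularity, so simulated call sets should carry a tiled mask
#' rather than one monolithic interval.
#'
#' @param L region length in bases.
#' @param tile interval width (default 5000 bp).
#' @return a \code{\link{region_mask}}.
#' @export
tiled_mask <- function(L, tile = 5000) {
  start <- seq(0, L - 1, by = tile)
  region_mask(start, pmin(start + tile, L))
}

as_iranges <- function(mask) {
  # 1-based closed coordinates covering the same bases
  IRanges::IRanges(start = as.integer(mask$start) + 1L,
                   end = as.integer(mask$end))
}

from_iranges <- function(ir) {
  # overlapping pieces merge, but adjacent intervals stay distinct so a
  # partitioned (e.g. tiled) mask keeps its interval boundaries
  ir <- IRanges::reduce(ir, min.gapwidth = 0L)
  region_mask(IRanges::start(ir) - 1L, IRanges::end(ir))
}

#' Mask arithmetic
#'
#' \code{mask_subtract} removes a set of intervals from a mask;
#' \code{mask_union} merges two masks; \code{pos_in_mask} tests 1-based
#' positions for membership; \code{mask_interval_of} returns, for each
#' position, the index of the containing interval (NA if outside).
#'
#' @param mask,other \code{\link{region_mask}} objects.
#' @param pos integer vector of 1-based positions.
#' @return a \code{region_mask}, or a logical/integer vector.
#' @export
mask_subtract <- function(mask, other) {
  if (length(other$start) == 0L) return(mask)
  mir <- as_iranges(mask)
  oir <- IRanges::reduce(as_iranges(other))
  hit <- unique(S4Vectors::queryHits(IRanges::findOverlaps(mir, oir)))
  if (!length(hit)) return(mask)
  pieces <- lapply(hit, function(i) IRanges::setdiff(mir[i], oir))
  out <- c(mir[-hit], do.call(c, pieces))
  out <- out[order(IRanges::start(out))]
  region_mask(IRanges::start(out) - 1L, IRanges::end(out))
}

#' @rdname mask_subtract
#' @export
mask_union <- function(mask, other) {
  from_iranges(IRanges::reduce(c(as_iranges(mask), as_iranges(other))))
}

#' @rdname mask_subtract
#' @export
pos_in_mask <- function(pos, mask) {
  !is.na(mask_interval_of(pos, mask))
}

#' @rdname mask_subtract
#' @export
mask_interval_of <- function(pos, mask) {
  if (length(mask$start) == 0L) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos - 1, mask$start)   # 0-based position vs starts
  inside <- i >= 1L & (pos - 1) < mask$end[pmax(i, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[inside] <- i[inside]
  out
}

#' Haploid genotype matrix
#'
#' Site-by-sample binary call matrix: 0 = ancestral, 1 = derived, NA =
#' missing (no-call). Rows are sites ordered by position (positions may
#' repeat when several alternative alleles segregate at one base; each
#' allele is carried as its own site). Carries per-sample sequencing
#' platform labels and the callable-region mask.
#'
#' @param geno integer matrix (sites x samples) of 0/1/NA calls.
#' @param pos 1-based site positions, non-decreasing.
#' @param samples sample names (default: column names of \code{geno}).
#' @param platform named character vector of per-sample platform labels;
#'   defaults to a single shared label.
#' @param mask a \code{\link{region_mask}}; defaults to one interval
#'   covering \code{[0, max(pos))}.
#' @return an object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(geno, pos, samples = colnames(geno),
                        platform = NULL, mask = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(geno)))
  if (nrow(geno) != length(pos)) stop("pos length must match site count")
  if (length(pos) && is.unsorted(pos)) {
    o <- order(pos)
    pos <- pos[o]; geno <- geno[o, , drop = FALSE]
  }
  if (any(geno[!is.na(geno)] %notin% c(0L, 1L)))
    stop("genotypes must be 0, 1 or NA")
  if (is.null(platform))
    platform <- setNames(rep("WGS", ncol(geno)), samples)
  if (is.null(mask))
    mask <- region_mask(0, max(c(pos, 1)))
  colnames(geno) <- samples
  structure(list(geno = geno, pos = as.numeric(pos), samples = samples,
                 platform = platform, mask = mask),
            class = "geno_matrix")
}

`%notin%` <- function(x, table) !(x %in% table)

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "sites x", ncol(x$geno), "samples;",
      format(callable_length(x$mask), big.mark = ","), "callable bases\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

# keep a subset of sites (logical or integer index), preserving order
gm_subset_sites <- function(gm, idx) {
  gm$geno <- gm$geno[idx, , drop = FALSE]
  gm$pos <- gm$pos[idx]
  gm
}

# drop sample columns by name
gm_drop_samples <- function(gm, drop) {
  keep <- setdiff(gm$samples, drop)
  gm$geno <- gm$geno[, keep, drop = FALSE]
  gm$samples <- keep
  gm$platform <- gm$platform[keep]
  gm
}
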