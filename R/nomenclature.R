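#' ISOGG-style branch naming of a haplotree
#'
#' Applies the hierarchical naming convention used for Y-chromosome
#' haplotrees: at every split the children are ranked by descendant tip
#' count (the major branch first; ties broken alphabetically by the
#' branch's chosen marker name) and receive suffixes that alternate
#' letters and numbers with depth, so the major path of e.g. "J1" runs
#' "J1a", "J1a1", "J1a1a", ... Minor branches take later letters or
#' numbers. Each named branch is additionally labelled with a defining
#' marker, preferring markers flagged as genotyped, otherwise the
#' lexicographically smallest; sites without a curated name get a
#' synthetic "M<position>" marker. Single-child chains collapse: the
#' child inherits its parent's name.
#'
#' @param tree rooted \code{phylo}.
#' @param assignment a \code{\link{map_sites_to_branches}} result giving
#'   each branch's defining sites.
#' @param haplogroup_label name of the root (default "J1").
#' @param marker_names optional data.frame with columns \code{pos},
#'   \code{marker} and (optionally) \code{genotyped}; duplicate marker
#'   names are an error.
#' @return list: \code{tree} (with \code{node.label} set to full labels)
#'   and \code{table}, a data.frame of \code{node}, \code{name},
#'   \code{marker}, \code{label}, \code{n_defining}, \code{n_tips}.
#' @export
annotate_branch_names <- function(tree, assignment,
                                  haplogroup_label = "J1",
                                  marker_names = NULL) {
  if (!is.null(marker_names)) {
    if (anyDuplicated(marker_names$marker))
      stop("duplicate marker names")
    if (is.null(marker_names$genotyped)) marker_names$genotyped <- FALSE
  }
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  tu <- tips_under(tree)
  ch <- children_list(tree)
  def_sites <- vector("list", nn)
  ok <- !assignment$recurrent & !is.na(assignment$branch)
  sp <- split(assignment$pos[ok], assignment$branch[ok])
  def_sites[as.integer(names(sp))] <- sp

  marker_of <- function(node) {
    ps <- def_sites[[node]]
    if (is.null(ps) || !length(ps)) return(NA_character_)
    mk <- paste0("M", ps)
    gt <- rep(FALSE, length(ps))
    if (!is.null(marker_names)) {
      hit <- match(ps, marker_names$pos)
      mk[!is.na(hit)] <- marker_names$marker[hit[!is.na(hit)]]
      gt[!is.na(hit)] <- marker_names$genotyped[hit[!is.na(hit)]]
    }
    if (any(gt)) sort(mk[gt])[1L] else sort(mk)[1L]
  }

  name <- character(nn)
  marker <- vapply(seq_len(nn), marker_of, "")
  rt <- root_node(tree)
  suffix <- function(rank, use_letters) {
    if (use_letters) {
      if (rank <= 26L) letters[rank]
      else paste0(letters[(rank - 1L) %/% 26L], letters[(rank - 1L) %% 26L + 1L])
    } else as.character(rank)
  }
  walk <- function(node, nm, depth) {
    name[node] <<- nm
    kids <- ch[[node]]
    if (is.null(kids) || !length(kids)) return(invisible())
    if (length(kids) == 1L) {           # unifurcation: inherit name
      walk(kids[1L], nm, depth)
      return(invisible())
    }
    mk <- marker[kids]
    no_marker <- is.na(mk) | mk == ""
    mk[no_marker] <- ""
    o <- order(-lengths(tu[kids]), no_marker, mk)
    kids <- kids[o]
    for (r in seq_along(kids))
      walk(kids[r], paste0(nm, suffix(r, depth %% 2L == 0L)), depth + 1L)
    invisible()
  }
  walk(rt, haplogroup_label, 0L)
  label <- ifelse(is.na(marker) | marker == "", name,
                  paste0(name, "-", marker))
  tab <- data.frame(node = seq_len(nn), name = name, marker = marker,
                    label = label,
                    n_defining = vapply(def_sites,
                                        function(x) length(x %||% integer(0)),
                                        1L),
                    n_tips = lengths(tu))
  tree$node.label <- label[(n + 1L):nn]
  list(tree = tree, table = tab[tab$name != "", , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a branch name back into its major/minor path
#'
#' Splits an ISOGG-style name such as "J1a2b1" into the haplogroup label
#' and the sequence of suffix choices, the inverse of the naming walk.
#'
#' @param name branch name (without the "-marker" part).
#' @param haplogroup_label the root label the name starts with.
#' @return character vector of suffix tokens (letters and numbers).
#' @export
parse_branch_name <- function(name, haplogroup_label = "J1") {
  if (!startsWith(name, haplogroup_label))
    stop("name does not start with the haplogroup label")
  rest <- substring(name, nchar(haplogroup_label) + 1L)
  toks <- regmatches(rest, gregexpr("[a-z]+|[0-9]+", rest))[[1L]]
  toks
}
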