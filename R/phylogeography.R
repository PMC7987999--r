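#' Prune recent same-population duplicates
#'
#' For every cherry (pair of sister tips) from the same population whose
#' coalescence is younger than \code{threshold_years}, one tip is removed
#' -- the one with more missing data (column \code{missing} of the
#' metadata, when present), ties broken by dropping the second sample ID
#' in sort order. Applied repeatedly until stable.
#'
#' @param tree dated \code{phylo}.
#' @param tip_metadata data.frame with columns \code{sample},
#'   \code{population} and optionally \code{missing}.
#' @param threshold_years age bound in years (default 1000).
#' @return the pruned \code{phylo}.
#' @export
prune_recent_same_population <- function(tree, tip_metadata,
                                         threshold_years = 1000) {
  md <- tip_metadata
  if (is.null(md$missing)) md$missing <- 0
  repeat {
    ages <- node_ages(tree)
    ch <- children_list(tree)
    n <- length(tree$tip.label)
    drop <- NULL
    for (v in (n + 1L):(n + tree$Nnode)) {
      kids <- ch[[v]]
      tips <- kids[kids <= n]
      if (length(kids) != 2L || length(tips) != 2L) next
      s <- tree$tip.label[tips]
      p <- md$population[match(s, md$sample)]
      if (length(unique(p)) != 1L || any(is.na(p))) next
      if (ages[v] >= threshold_years) next
      miss <- md$missing[match(s, md$sample)]
      drop <- if (miss[1L] > miss[2L]) s[1L]
              else if (miss[2L] > miss[1L]) s[2L]
              else sort(s)[2L]
      break
    }
    if (is.null(drop)) return(tree)
    tree <- ape::drop.tip(tree, drop)
  }
}

#' Sample ancestral locations under Brownian diffusion
#'
#' Continuous-space phylogeography on a dated tree: tip coordinates are
#' projected onto a km plane centred at their centroid; for each draw the
#' squared diffusion rate is sampled from its conditional
#' (scaled-inverse-chi-squared, Jeffreys prior, pooled over both axes via
#' phylogenetic contrasts) and internal-node locations are then drawn
#' from their exact conditional Gaussian given the tips by an
#' upward-filtering, downward-sampling pass. Coincident tip coordinates
#' are jittered by up to \code{jitter_km}.
#'
#' @param tree dated \code{phylo} (or list of dated trees: posterior
#'   topology/age states cycled over draws).
#' @param tip_locations data.frame with \code{sample}, \code{lat},
#'   \code{lon}.
#' @param n_draws number of posterior draws (default 500).
#' @param jitter_km jitter radius for duplicate coordinates (default 1).
#' @param seed integer seed.
#' @return object of class \code{geo_sample}: list with \code{lat},
#'   \code{lon} (draw x node matrices), \code{sigma2} (km^2/year draws),
#'   \code{trees}, \code{origin}, \code{tree_index}.
#' @export
infer_locations <- function(tree, tip_locations, n_draws = 500,
                            jitter_km = 1, seed = 1L) {
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  t1 <- trees[[1L]]
  miss <- setdiff(t1$tip.label, tip_locations$sample)
  if (length(miss))
    stop("missing tip coordinates: ", paste(miss, collapse = ", "))
  set.seed(.yc_check_seed(seed))
  idx <- match(t1$tip.label, tip_locations$sample)
  lat <- tip_locations$lat[idx]; lon <- tip_locations$lon[idx]
  origin <- c(mean(lat), mean(lon))
  xy <- geo_project(lat, lon, origin)
  dup <- duplicated(paste(xy$x, xy$y))
  if (any(dup)) {
    ang <- runif(sum(dup), 0, 2 * pi)
    r <- jitter_km * sqrt(runif(sum(dup)))
    xy$x[dup] <- xy$x[dup] + r * cos(ang)
    xy$y[dup] <- xy$y[dup] + r * sin(ang)
  }
  n <- length(t1$tip.label)
  nn <- n + t1$Nnode
  X <- matrix(NA_real_, n_draws, nn)
  Y <- matrix(NA_real_, n_draws, nn)
  sig2 <- numeric(n_draws)
  tindex <- rep(seq_along(trees), length.out = n_draws)

  sample_state <- function(tr) {
    ch <- children_list(tr)
    pv <- parent_vec(tr)
    eln <- numeric(nn)
    eln[tr$edge[, 2L]] <- pmax(tr$edge.length, 1e-8)
    ord <- unique(ape::reorder.phylo(tr, "postorder")$edge[, 1L])
    m_x <- m_y <- v_up <- numeric(nn)   # children-folded messages
    m_x[seq_len(n)] <- xy$x; m_y[seq_len(n)] <- xy$y
    S <- 0; ncon <- 0L
    for (p in ord) {
      kids <- ch[[p]]
      mx <- m_x[kids[1L]]; my <- m_y[kids[1L]]
      vv <- v_up[kids[1L]] + eln[kids[1L]]
      if (length(kids) > 1L) for (k in kids[-1L]) {
        vk <- v_up[k] + eln[k]
        S <- S + ((mx - m_x[k])^2 + (my - m_y[k])^2) / (vv + vk)
        ncon <- ncon + 1L
        w <- vk / (vv + vk)
        mx <- w * mx + (1 - w) * m_x[k]
        my <- w * my + (1 - w) * m_y[k]
        vv <- vv * vk / (vv + vk)
      }
      m_x[p] <- mx; m_y[p] <- my; v_up[p] <- vv
    }
    s2 <- S / rchisq(1, df = 2 * ncon)  # Jeffreys posterior, both axes
    rt <- root_node(tr)
    sx <- sy <- numeric(nn)
    sx[seq_len(n)] <- xy$x; sy[seq_len(n)] <- xy$y
    sx[rt] <- rnorm(1, m_x[rt], sqrt(s2 * v_up[rt]))
    sy[rt] <- rnorm(1, m_y[rt], sqrt(s2 * v_up[rt]))
    pre <- ape::reorder.phylo(tr, "cladewise")$edge
    for (j in seq_len(nrow(pre))) {
      v <- pre[j, 2L]
      if (v <= n) next
      p <- pre[j, 1L]
      prec <- 1 / v_up[v] + 1 / eln[v]
      mm_x <- (m_x[v] / v_up[v] + sx[p] / eln[v]) / prec
      mm_y <- (m_y[v] / v_up[v] + sy[p] / eln[v]) / prec
      sdv <- sqrt(s2 / prec)
      sx[v] <- rnorm(1, mm_x, sdv)
      sy[v] <- rnorm(1, mm_y, sdv)
    }
    list(x = sx, y = sy, s2 = s2)
  }

  for (d in seq_len(n_draws)) {
    st <- sample_state(trees[[tindex[d]]])
    X[d, ] <- st$x; Y[d, ] <- st$y; sig2[d] <- st$s2
  }
  ll <- geo_unproject(as.vector(X), as.vector(Y), origin)
  structure(list(lat = matrix(ll$lat, n_draws, nn),
                 lon = matrix(ll$lon, n_draws, nn),
                 x = X, y = Y, sigma2 = sig2, trees = trees,
                 tree_index = tindex, origin = origin,
                 n_tips = n),
            class = "geo_sample")
}

#' @export
print.geo_sample <- function(x, ...) {
  cat("geo_sample:", nrow(x$lat), "draws over",
      ncol(x$lat) - x$n_tips, "internal nodes\n")
  invisible(x)
}

#' 2-D highest posterior density region
#'
#' Gaussian-kernel density of the sampled locations on a regular grid;
#' the region is the smallest set of cells whose summed mass reaches
#' \code{level}, contoured to polygons, with the area obtained by cell
#' summation (km^2 using the local degree scale).
#'
#' @param root_samples data.frame (or matrix) with \code{lat},
#'   \code{lon} columns; at least 100 rows.
#' @param level probability level (default 0.80).
#' @param n_grid grid cells per axis (default 200).
#' @return object of class \code{hpd_region}: list with \code{level},
#'   \code{threshold}, \code{polygons} (list of lon/lat rings),
#'   \code{area_km2}, \code{grid}.
#' @export
hpd_region_2d <- function(root_samples, level = 0.80, n_grid = 200) {
  root_samples <- as.data.frame(root_samples)
  lat <- root_samples$lat
  lon <- root_samples$lon
  if (length(lat) < 100L) stop("need at least 100 location samples")
  if (sd(lat) == 0 && sd(lon) == 0) {   # all identical: single cell
    eps <- 1e-3
    poly <- list(data.frame(lon = lon[1L] + eps * c(-1, 1, 1, -1),
                            lat = lat[1L] + eps * c(-1, -1, 1, 1)))
    return(structure(list(level = level, threshold = Inf, polygons = poly,
                          area_km2 = 0, grid = NULL),
                     class = "hpd_region"))
  }
  pad <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) w <- max(abs(r[1L]), 1e-3)
    r + c(-0.35, 0.35) * w
  }
  kd <- MASS::kde2d(lon, lat, n = n_grid, lims = c(pad(lon), pad(lat)))
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  mass <- kd$z * dx * dy
  mass <- mass / sum(mass)
  o <- order(kd$z, decreasing = TRUE)
  cum <- cumsum(mass[o])
  kcut <- which(cum >= level)[1L]
  threshold <- kd$z[o[kcut]]
  sel <- kd$z >= threshold
  midlat <- mean(lat)
  cell_km2 <- (dx * 111.3195 * cos(midlat * pi / 180)) * (dy * 111.3195)
  area <- sum(sel) * cell_km2
  cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = threshold)
  polygons <- lapply(cl, function(p) data.frame(lon = p$x, lat = p$y))
  structure(list(level = level, threshold = threshold, polygons = polygons,
                 area_km2 = area, grid = kd, mass_in_region = cum[kcut]),
            class = "hpd_region")
}

#' Does an HPD region contain a point?
#'
#' Nearest-grid-cell density lookup against the region threshold.
#'
#' @param region an \code{\link{hpd_region_2d}} result.
#' @param lat,lon query point in degrees.
#' @return logical.
#' @export
hpd_region_contains <- function(region, lat, lon) {
  if (is.null(region$grid)) {
    p <- region$polygons[[1L]]
    return(lat >= min(p$lat) && lat <= max(p$lat) &&
             lon >= min(p$lon) && lon <= max(p$lon))
  }
  kd <- region$grid
  if (lon < min(kd$x) || lon > max(kd$x) ||
      lat < min(kd$y) || lat > max(kd$y)) return(FALSE)
  i <- which.min(abs(kd$x - lon))
  j <- which.min(abs(kd$y - lat))
  kd$z[i, j] >= region$threshold
}

#' Posterior diffusion-rate samples
#'
#' Per posterior location draw: total great-circle displacement along
#' all branches divided by total branch time, in km/year.
#'
#' @param geo a \code{\link{infer_locations}} result.
#' @return numeric vector of km/year samples with a \code{summary}
#'   attribute (median and 95 percent HPD).
#' @export
diffusion_rate <- function(geo) {
  rates <- numeric(nrow(geo$lat))
  for (d in seq_len(nrow(geo$lat))) {
    tr <- geo$trees[[geo$tree_index[d]]]
    tt <- sum(tr$edge.length)
    if (tt <= 0) stop("zero total tree time")
    p <- tr$edge[, 1L]; ch <- tr$edge[, 2L]
    dist <- haversine_km(geo$lat[d, p], geo$lon[d, p],
                         geo$lat[d, ch], geo$lon[d, ch])
    rates[d] <- sum(dist) / tt
  }
  if (length(rates) >= 2L)
    attr(rates, "summary") <- c(median = median(rates),
                                hpd_interval(rates, 0.95))
  rates
}
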