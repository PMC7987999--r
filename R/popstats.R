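#' Nei's unbiased gene diversity of STR haplotypes
#'
#' \code{D = n/(n-1) * (1 - sum(p_i^2))} over haplotype frequencies,
#' where haplotype identity is exact equality across all loci. Equals the
#' probability that two randomly drawn haplotypes differ, bias-corrected.
#'
#' @param haplotypes an \code{str_table}, or a matrix/data.frame of
#'   repeat counts (samples x loci) with no missing values.
#' @return diversity in [0, 1].
#' @export
str_gene_diversity <- function(haplotypes) {
  m <- if (inherits(haplotypes, "str_table")) haplotypes$repeats
       else as.matrix(haplotypes)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 haplotypes")
  if (anyNA(m)) stop("missing loci are not allowed")
  key <- apply(m, 1L, paste, collapse = "|")
  p <- as.numeric(table(key)) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Branch frequency table per population
#'
#' Counts and percentages of samples per population and branch at one
#' chosen tree level; branches must partition the samples.
#'
#' @param assignments data.frame with \code{sample}, \code{branch}.
#' @param population_labels data.frame with \code{sample},
#'   \code{population} (or a named vector).
#' @param level_branches optional subset of branch names defining the
#'   level; a sample matching several level branches is an error.
#' @return data.frame of populations x branches with \code{n_<branch>}
#'   and \code{pct_<branch>} columns plus a \code{Total} row.
#' @export
branch_frequency_table <- function(assignments, population_labels,
                                   level_branches = NULL) {
  if (!is.data.frame(population_labels))
    population_labels <- data.frame(sample = names(population_labels),
                                    population = unname(population_labels))
  df <- merge(assignments, population_labels, by = "sample")
  if (!is.null(level_branches)) {
    if (anyDuplicated(level_branches))
      stop("overlapping level branches")
    hits <- vapply(df$branch, function(b)
      sum(startsWith(b, level_branches) |
            level_branches == b), 1L)
    if (any(hits > 1L))
      stop("overlapping level branches: a sample matches several")
    lab <- rep("other", nrow(df))
    for (lb in level_branches)
      lab[df$branch == lb | startsWith(df$branch, lb)] <- lb
    df$branch <- lab
  }
  tab <- table(df$population, df$branch)
  cnt <- as.data.frame.matrix(tab)
  total <- colSums(cnt)
  cnt <- rbind(cnt, Total = total)
  pct <- 100 * sweep(cnt, 1L, rowSums(cnt), "/")
  out <- data.frame(population = rownames(cnt), check.names = FALSE)
  for (b in colnames(cnt)) {
    out[[paste0("n_", b)]] <- cnt[[b]]
    out[[paste0("pct_", b)]] <- round(pct[[b]], 2)
  }
  rownames(out) <- NULL
  out
}

#' Spatial interpolation surface (IDW or ordinary kriging)
#'
#' Interpolates point-wise frequencies or diversities onto a regular
#' lon/lat grid. \code{idw}: inverse-distance weighting with power
#' \code{idw_power}. \code{ordinary_kriging}: ordinary kriging with a
#' linear variogram (gamma(h) = h; the slope cancels in the weights) and
#' no nugget, so the surface interpolates the data exactly. Distances
#' are great-circle km. Duplicate coordinates with different values are
#' averaged with a warning.
#'
#' @param points data.frame with \code{lat}, \code{lon}, \code{value}.
#' @param grid_spec list with \code{lon} and \code{lat} grid vectors, or
#'   \code{n} (cells per axis, default 50) to span the data with 10
#'   percent padding.
#' @param method \code{"ordinary_kriging"} (default) or \code{"idw"}.
#' @param idw_power IDW exponent (default 2).
#' @return object of class \code{surface_grid}: list with \code{lon},
#'   \code{lat}, \code{values} (lon x lat matrix), \code{method}.
#' @export
interpolate_surface <- function(points, grid_spec = list(n = 50),
                                method = c("ordinary_kriging", "idw"),
                                idw_power = 2) {
  method <- match.arg(method)
  pts <- points[, c("lat", "lon", "value")]
  if (any(!is.finite(pts$value))) stop("values must be finite")
  key <- paste(pts$lat, pts$lon)
  if (anyDuplicated(key)) {
    if (max(tapply(pts$value, key, function(v) diff(range(v)))) > 0)
      warning("duplicate coordinates with different values: averaged")
    pts <- aggregate(value ~ lat + lon, pts, mean)
  }
  np <- nrow(pts)
  if (method == "ordinary_kriging") {
    if (np < 3L) stop("kriging needs at least 3 points")
    M <- cbind(pts$lon, pts$lat, 1)
    if (qr(M)$rank < 3L) stop("kriging needs non-collinear points")
  }
  if (is.null(grid_spec$lon)) {
    n <- grid_spec$n %||% 50
    padx <- 0.1 * max(diff(range(pts$lon)), 0.1)
    pady <- 0.1 * max(diff(range(pts$lat)), 0.1)
    grid_spec <- list(lon = seq(min(pts$lon) - padx, max(pts$lon) + padx,
                                length.out = n),
                      lat = seq(min(pts$lat) - pady, max(pts$lat) + pady,
                                length.out = n))
  }
  gx <- grid_spec$lon; gy <- grid_spec$lat
  G <- expand.grid(lon = gx, lat = gy)
  D <- outer(seq_len(np), seq_len(nrow(G)), function(i, j)
    haversine_km(pts$lat[i], pts$lon[i], G$lat[j], G$lon[j]))
  vals <- numeric(nrow(G))
  if (method == "idw") {
    for (j in seq_len(nrow(G))) {
      d <- D[, j]
      if (any(d < 1e-9)) vals[j] <- pts$value[which.min(d)]
      else {
        w <- 1 / d^idw_power
        vals[j] <- sum(w * pts$value) / sum(w)
      }
    }
  } else {
    Dpp <- outer(seq_len(np), seq_len(np), function(i, j)
      haversine_km(pts$lat[i], pts$lon[i], pts$lat[j], pts$lon[j]))
    A <- rbind(cbind(Dpp, 1), c(rep(1, np), 0))
    B <- rbind(D, 1)
    W <- solve(A, B)
    vals <- as.numeric(crossprod(W[seq_len(np), , drop = FALSE],
                                 pts$value))
    exact <- apply(D, 2L, function(d) {
      i <- which(d < 1e-9)
      if (length(i)) i[1L] else NA_integer_
    })
    vals[!is.na(exact)] <- pts$value[exact[!is.na(exact)]]
  }
  structure(list(lon = gx, lat = gy,
                 values = matrix(vals, length(gx), length(gy)),
                 method = method, points = pts),
            class = "surface_grid")
}

#' Kriging weights for a set of prediction points
#'
#' Exposes the ordinary-kriging linear system (linear variogram, no
#' nugget) for inspection: returns the weight vector and Lagrange
#' multiplier for one target location.
#'
#' @param points data.frame with \code{lat}, \code{lon}.
#' @param target numeric \code{c(lat, lon)}.
#' @return list with \code{weights} (sums to 1) and \code{lagrange}.
#' @export
kriging_weights <- function(points, target) {
  np <- nrow(points)
  Dpp <- outer(seq_len(np), seq_len(np), function(i, j)
    haversine_km(points$lat[i], points$lon[i], points$lat[j], points$lon[j]))
  d0 <- haversine_km(points$lat, points$lon, target[1], target[2])
  A <- rbind(cbind(Dpp, 1), c(rep(1, np), 0))
  sol <- solve(A, c(d0, 1))
  list(weights = sol[seq_len(np)], lagrange = sol[np + 1L])
}

#' Write a surface grid as an ESRI ASCII raster
#'
#' @param surface a \code{\link{interpolate_surface}} result on a
#'   uniformly spaced grid with equal lon/lat cell size.
#' @param path output file.
#' @export
write_surface_asc <- function(surface, path) {
  dx <- diff(surface$lon[1:2]); dy <- diff(surface$lat[1:2])
  if (abs(dx - dy) > 1e-9 * max(dx, dy))
    stop("ESRI ASCII grids require square cells")
  z <- t(surface$values)[rev(seq_along(surface$lat)), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", length(surface$lon)),
               paste("nrows", length(surface$lat)),
               paste("xllcorner", surface$lon[1] - dx / 2),
               paste("yllcorner", surface$lat[1] - dy / 2),
               paste("cellsize", dx),
               "NODATA_value -9999"), con)
  write.table(round(z, 6), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
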