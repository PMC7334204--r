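#' Reference bandwidth for a bivariate normal kernel
#'
#' The ad-hoc ("reference") bandwidth used as default by home-range
#' kernel software: `href = sqrt((var(x) + var(y)) / 2) * n^(-1/6)`.
#'
#' @param x,y point coordinates in metres.
#' @return Bandwidth in metres.
#' @export
href_bandwidth <- function(x, y) {
  n <- length(x)
  sqrt((var(x) + var(y)) / 2) * n^(-1 / 6)
}

#' Fit a kernel density surface to a participant's record locations
#'
#' Bivariate-normal product-kernel density estimate on a regular grid.
#' The grid covers the points' bounding box padded by `pad_factor`
#' bandwidths on every side, which keeps the mass lost off-grid below
#' about 1%; the surface is then normalised so its grid integral is 1.
#'
#' @param points matrix or data.frame with columns `x`, `y` in metres.
#' @param bandwidth kernel standard deviation in metres, or `"href"`
#'   (default) for the reference bandwidth.
#' @param grid_n grid resolution per axis (default 256).
#' @param pad_factor extent padding in bandwidths (default 3).
#' @param min_points minimum number of distinct locations (default 5);
#'   below it, or with zero variance on both axes, the KDE (and hence the
#'   spatial metrics) is undefined and `NULL` is returned with a warning.
#' @return A `density_surface`: list with grid axes `x`, `y`, density
#'   matrix `z` (rows index `x`), cell sizes `dx`, `dy`, `bandwidth`,
#'   `n_points`; or `NULL` when undefined.
#' @export
fit_kde <- function(points, bandwidth = "href", grid_n = 256,
                    pad_factor = 3, min_points = 5) {
  pts <- as.data.frame(points)
  x <- as.numeric(pts$x); y <- as.numeric(pts$y)
  n <- length(x)
  n_distinct <- nrow(unique(cbind(x, y)))
  if (n_distinct < min_points || (var(x) == 0 && var(y) == 0)) {
    warning("fit_kde: fewer than ", min_points,
            " distinct locations (or zero spread); spatial metrics undefined")
    return(NULL)
  }
  h <- if (identical(bandwidth, "href")) href_bandwidth(x, y) else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0) {
    warning("fit_kde: non-positive bandwidth; spatial metrics undefined")
    return(NULL)
  }
  pad <- pad_factor * h
  gx <- seq(min(x) - pad, max(x) + pad, length.out = grid_n)
  gy <- seq(min(y) - pad, max(y) + pad, length.out = grid_n)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  # separable kernel: z = Kx %*% t(Ky) / n, with Kx[g, i] = dnorm(gx[g]; x_i, h)
  kx <- outer(gx, x, function(g, p) dnorm(g, mean = p, sd = h))
  ky <- outer(gy, y, function(g, p) dnorm(g, mean = p, sd = h))
  z <- (kx %*% t(ky)) / n
  mass <- sum(z) * dx * dy
  z <- z / mass
  structure(list(x = gx, y = gy, z = z, dx = dx, dy = dy,
                 bandwidth = h, n_points = n, raw_mass = mass),
            class = "density_surface")
}

#' Percent-volume isopleth of a density surface
#'
#' Finds the smallest-area region of the grid containing at least
#' `level` of the estimated density mass: grid cells are sorted by
#' density and accumulated greedily from the densest down until the
#' requested mass is reached (the standard percent-volume-contour
#' construction). The region's disjoint parts are the connected
#' components of the selected cells under 8-connectivity.
#'
#' @param surface a `density_surface` from [fit_kde()].
#' @param level mass fraction in (0, 1), e.g. 0.95 or 0.60.
#' @return List with `level`, `area_km2` (total region area),
#'   `n_parts` (disjoint polygon count), `threshold` (density at the
#'   contour) and `mask` (logical grid matrix of selected cells).
#' @export
isopleth <- function(surface, level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("isopleth: level must be a single number in (0, 1)")
  }
  cell_area <- surface$dx * surface$dy
  m <- surface$z * cell_area
  m <- m / sum(m)
  ord <- order(as.vector(m), decreasing = TRUE)
  cum <- cumsum(m[ord])
  k <- which(cum >= level)[1]
  threshold <- surface$z[ord[k]]
  mask <- surface$z >= threshold
  list(level = level,
       area_km2 = sum(mask) * cell_area / 1e6,
       n_parts = n_mask_components(mask),
       threshold = threshold,
       mask = mask)
}

# connected components of TRUE cells under 8-connectivity (holes in a
# part do not split it; diagonal contact joins)
n_mask_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0L)
  nr <- nrow(mask)
  nc <- ncol(mask)
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  edges <- list()
  for (dr in c(-1L, 0L, 1L)) {
    for (dc in c(0L, 1L)) {
      if (dc == 0L && dr <= 0L) next
      r2 <- row_i + dr; c2 <- col_i + dc
      ok <- r2 >= 1L & r2 <= nr & c2 <= nc
      if (!any(ok)) next
      j <- (c2[ok] - 1L) * nr + r2[ok]
      hit <- pos[j] > 0L
      if (any(hit)) {
        edges[[length(edges) + 1L]] <-
          cbind(pos[idx[ok]][hit], pos[j][hit])
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  igraph::components(g)$no
}

#' The three spatial metrics of a participant
#'
#' * `active_area_size`: area (km^2) of the 95% kernel density region,
#'   the minimum area estimated to contain the participant's next record
#'   with probability 0.95;
#' * `n_recording_areas`: number of discrete, non-intersecting parts of
#'   that region;
#' * `spatial_aggregation`: area of the 60% (core) region as a
#'   proportion of the 95% region, in (0, 1\]; small values mean records
#'   concentrate in a core with scattered records elsewhere.
#'
#' @inheritParams fit_kde
#' @param levels isopleth levels for the active area and core area.
#' @return List with the three metrics (all `NA` when the KDE is
#'   undefined for these points).
#' @export
spatial_metrics <- function(points, bandwidth = "href", grid_n = 256,
                            pad_factor = 3, min_points = 5,
                            levels = c(active = 0.95, core = 0.60)) {
  surf <- fit_kde(points, bandwidth = bandwidth, grid_n = grid_n,
                  pad_factor = pad_factor, min_points = min_points)
  if (is.null(surf)) {
    return(list(active_area_size = NA_real_, n_recording_areas = NA_integer_,
                spatial_aggregation = NA_real_))
  }
  iso95 <- isopleth(surf, levels[["active"]])
  iso60 <- isopleth(surf, levels[["core"]])
  list(active_area_size = iso95$area_km2,
       n_recording_areas = iso95$n_parts,
       spatial_aggregation = iso60$area_km2 / iso95$area_km2)
}

#' Spatial metrics for every participant in a record table
#' @param table a `record_table`.
#' @param ... passed to [spatial_metrics()].
#' @return `data.table` with `participant_id` and the three metrics.
#' @export
spatial_metrics_all <- function(table, ...) {
  dt <- as.data.table(table)
  ids <- sort(unique(dt$participant_id))
  rbindlist(lapply(ids, function(id) {
    m <- suppressWarnings(spatial_metrics(dt[participant_id == id, .(x, y)], ...))
    data.table(participant_id = id,
               active_area_size = m$active_area_size,
               n_recording_areas = as.integer(m$n_recording_areas),
               spatial_aggregation = m$spatial_aggregation)
  }))[]
}

#' Export isopleth outlines as GeoJSON
#'
#' Contour polygons of the density surface at the isopleth thresholds,
#' in the planar coordinates of the working CRS (recorded in the file's
#' `crs_tag` property).
#'
#' @param surface a `density_surface`.
#' @param levels isopleth levels to export.
#' @param path output file path.
#' @param crs_tag free-text CRS tag written into the file.
#' @return `path`, invisibly.
#' @export
export_isopleths_geojson <- function(surface, levels = c(0.95, 0.60), path,
                                     crs_tag = "metric") {
  features <- lapply(levels, function(lv) {
    iso <- isopleth(surface, lv)
    cl <- grDevices::contourLines(surface$x, surface$y, surface$z,
                                  levels = iso$threshold)
    rings <- lapply(cl, function(li) {
      xy <- cbind(li$x, li$y)
      if (!all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
      list(apply(xy, 1, as.list))
    })
    list(type = "Feature",
         properties = list(level = lv, area_km2 = iso$area_km2,
                           n_parts = iso$n_parts),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  obj <- list(type = "FeatureCollection", crs_tag = crs_tag, features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
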