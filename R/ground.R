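## Progressive TIN densification ground filter.

#' Ground filter parameters
#'
#' Defaults are the published processing parameters, identical for ALS
#' and TLS: terrain inclination 60 deg, iterative angle 6 deg, iterative
#' distance 0.6 m.
#'
#' @param terrain_inclination maximum slope (deg) tolerated between
#'   neighbouring seed minima (seed-sanity bound), in (0, 90).
#' @param iterative_angle acceptance angle to the TIN facet (deg), in (0, 90).
#' @param iterative_distance acceptance distance to the TIN facet (m), > 0.
#' @export
ground_filter_params <- function(terrain_inclination = 60,
                                 iterative_angle = 6,
                                 iterative_distance = 0.6) {
  if (terrain_inclination <= 0 || terrain_inclination >= 90 ||
      iterative_angle <= 0 || iterative_angle >= 90)
    stop_("angles must lie strictly between 0 and 90 degrees")
  if (iterative_distance <= 0) stop_("iterative_distance must be > 0")
  structure(list(terrain_inclination = terrain_inclination,
                 iterative_angle = iterative_angle,
                 iterative_distance = iterative_distance),
            class = "ground_filter_params")
}

## TIN surface elevation at query points; NA outside the hull is filled
## with the nearest-vertex elevation.
tin_surface <- function(gx, gy, gz, qx, qy) {
  if (length(qx) == 0L) return(numeric(0))
  ## interp emits benign notices on degenerate triangles; silence them
  z <- tryCatch(
    suppressWarnings(
      interp::interpp(gx, gy, gz, xo = qx, yo = qy, duplicate = "mean")$z),
    error = function(e) rep(NA_real_, length(qx)))
  if (anyNA(z)) {
    idx <- which(is.na(z))
    for (k in idx) {
      j <- which.min((gx - qx[k])^2 + (gy - qy[k])^2)
      z[k] <- gz[j]
    }
  }
  z
}

#' Classify ground points by progressive TIN densification
#'
#' Seed points are block minima over a coarse grid; the triangulated
#' seed surface is then densified iteratively: an unclassified point is
#' accepted as ground when its vertical offset to the TIN surface is at
#' most `iterative_distance` and the angle it subtends to the nearest
#' TIN vertex is at most `iterative_angle`.  Iteration stops when no
#' further points are accepted.
#'
#' @param cloud a [point_cloud].
#' @param params a [ground_filter_params].
#' @param seed_cell block-minimum grid size in m (largest non-ground
#'   object the filter must step over).
#' @param max_iter densification iteration cap.
#' @return The cloud with `class` set to `"ground"` / `"unclassified"`
#'   (prior labels are ignored).
#' @export
filter_ground <- function(cloud, params = ground_filter_params(),
                          seed_cell = 5, max_iter = 25L) {
  n <- n_points(cloud)
  if (n == 0L) return(point_cloud(cloud$points[0, , drop = FALSE],
                                  character(0), cloud$source,
                                  cloud$nominal_density))
  x <- cloud$points[, 1]; y <- cloud$points[, 2]; z <- cloud$points[, 3]
  ## block minima seeds
  ci <- floor(x / seed_cell); cj <- floor(y / seed_cell)
  key <- paste(ci, cj)
  seed_idx <- vapply(split(seq_len(n), key),
                     function(ii) ii[which.min(z[ii])], integer(1))
  seed_idx <- unname(seed_idx)
  ## degenerate geometry check
  sx <- x[seed_idx]; sy <- y[seed_idx]
  if (length(seed_idx) < 3L ||
      abs(stats::sd(sx) * stats::sd(sy)) < 1e-12 ||
      isTRUE(abs(stats::cor(sx, sy)) > 1 - 1e-9))
    stop_("degenerate input: seed points are collinear; cannot build a TIN")
  ## seed sanity: drop seeds steeper than terrain_inclination to all
  ## neighbouring seeds (low outliers below the terrain)
  if (length(seed_idx) >= 4L) {
    tan_inc <- tan(params$terrain_inclination * pi / 180)
    keep <- vapply(seq_along(seed_idx), function(k) {
      d <- sqrt((sx - sx[k])^2 + (sy - sy[k])^2)
      nb <- order(d)[2:min(5, length(d))]
      any(abs(z[seed_idx[k]] - z[seed_idx[nb]]) / pmax(d[nb], 1e-9) <= tan_inc)
    }, logical(1))
    if (sum(keep) >= 3L) seed_idx <- seed_idx[keep]
  }
  ground <- logical(n)
  ground[seed_idx] <- TRUE
  tan_ang <- tan(params$iterative_angle * pi / 180)
  for (it in seq_len(max_iter)) {
    cand <- which(!ground)
    if (!length(cand)) break
    gi <- which(ground)
    ## decimate the TIN vertex set to per-cell minima (~1 m facets);
    ## keeps the triangulation small as the ground set densifies
    dec <- max(seed_cell / 5, 1)
    dkey <- paste(floor(x[gi] / dec), floor(y[gi] / dec))
    verts <- gi[vapply(split(seq_along(gi), dkey),
                       function(ii) ii[which.min(z[gi][ii])], integer(1))]
    surf <- tin_surface(x[verts], y[verts], z[verts], x[cand], y[cand])
    dz <- z[cand] - surf
    dnn <- grid_dist_to_set(x[cand], y[cand], x[verts], y[verts], cell = 1,
                            cap = params$iterative_distance / tan_ang + 1)
    ## angle to the nearest TIN vertex; the 1 m floor avoids the
    ## vertex-adjacent degeneracy (angle -> 90 deg as distance -> 0)
    ok <- abs(dz) <= params$iterative_distance &
      abs(dz) <= tan_ang * pmax(dnn, 1)
    if (!any(ok)) break
    ground[cand[ok]] <- TRUE
  }
  cls <- ifelse(ground, "ground", "unclassified")
  point_cloud(cloud$points, cls, cloud$source, cloud$nominal_density)
}

#' Build a digital elevation model from ground points
#'
#' Per-cell minimum elevation of ground-classified points; empty cells
#' are filled by TIN interpolation from the occupied cell minima
#' (nearest-value beyond the hull).
#'
#' @param cloud a classified [point_cloud] (needs `"ground"` labels).
#' @param cell_size DEM cell size in m, > 0.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; default: cloud
#'   bounding box.
#' @return A [raster_grid] of ground elevation.
#' @export
build_dem <- function(cloud, cell_size, extent = NULL) {
  if (cell_size <= 0) stop_("cell_size must be > 0")
  gi <- cloud$class == "ground"
  if (!any(gi)) stop_("no ground points: run filter_ground() first")
  grid <- empty_grid(cloud, cell_size, extent)
  gx <- cloud$points[gi, 1]; gy <- cloud$points[gi, 2]; gz <- cloud$points[gi, 3]
  rc <- rg_rowcol(grid, gx, gy)
  lin <- (rc$col - 1L) * grid$n_rows + rc$row
  mins <- tapply(gz, lin, min)
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vals[as.integer(names(mins))] <- mins
  if (anyNA(vals)) {
    cc <- rg_centers(grid)
    filled <- which(!is.na(vals))
    fr <- ((filled - 1L) %% grid$n_rows) + 1L
    fc <- ((filled - 1L) %/% grid$n_rows) + 1L
    holes <- which(is.na(vals))
    hr <- ((holes - 1L) %% grid$n_rows) + 1L
    hc <- ((holes - 1L) %/% grid$n_rows) + 1L
    vals[holes] <- tin_surface(cc$x[fc], cc$y[fr], vals[filled],
                               cc$x[hc], cc$y[hr])
  }
  grid$values <- vals
  grid
}

empty_grid <- function(cloud, cell_size, extent = NULL) {
  if (is.null(extent)) {
    extent <- c(min(cloud$points[, 1]), max(cloud$points[, 1]),
                min(cloud$points[, 2]), max(cloud$points[, 2]))
  }
  ncol <- max(1L, ceiling((extent[2] - extent[1]) / cell_size))
  nrow <- max(1L, ceiling((extent[4] - extent[3]) / cell_size))
  raster_grid(origin = c(extent[1], extent[3] + nrow * cell_size),
              cell_size = cell_size,
              values = matrix(NA_real_, nrow, ncol))
}

#' Build a canopy height model
#'
#' Per-cell maximum point elevation minus the DEM, floored at zero;
#' cells without points get height 0.
#'
#' @param cloud a [point_cloud] (all classes are used).
#' @param dem a [raster_grid] from [build_dem()].
#' @param cell_size CHM cell size in m; default: the DEM's.
#' @return A [raster_grid] of canopy height above ground.
#' @export
build_chm <- function(cloud, dem, cell_size = dem$cell_size) {
  grid <- empty_grid(cloud, cell_size,
                     extent = c(dem$origin[1],
                                dem$origin[1] + dem$n_cols * dem$cell_size,
                                dem$origin[2] - dem$n_rows * dem$cell_size,
                                dem$origin[2]))
  x <- cloud$points[, 1]; y <- cloud$points[, 2]; z <- cloud$points[, 3]
  rc <- rg_rowcol(grid, x, y)
  lin <- (rc$col - 1L) * grid$n_rows + rc$row
  maxs <- tapply(z, lin, max)
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vals[as.integer(names(maxs))] <- maxs
  cc <- rg_centers(grid)
  dem_at <- outer(cc$y, cc$x, function(Y, X) rg_value_at(dem, X, Y))
  vals <- pmax(vals - dem_at, 0)
  vals[is.na(vals)] <- 0
  grid$values <- vals
  grid
}

#' Normalize point heights above ground
#'
#' Subtracts the DEM elevation from each point's z, flooring at 0.
#'
#' @param cloud a [point_cloud].
#' @param dem a [raster_grid].
#' @return The cloud with z replaced by height above ground.
#' @export
normalize_heights <- function(cloud, dem) {
  z0 <- rg_value_at(dem, cloud$points[, 1], cloud$points[, 2])
  pts <- cloud$points
  pts[, 3] <- pmax(pts[, 3] - z0, 0)
  point_cloud(pts, cloud$class, cloud$source, cloud$nominal_density)
}

#' Vegetation height bounds
#'
#' Published defaults: ALS 2-80 m, TLS 0.2-50 m; both bounds inclusive.
#'
#' @param lower_height,upper_height height window in m, 0 <= lower < upper.
#' @export
vegetation_params <- function(lower_height = 2, upper_height = 80) {
  if (lower_height < 0 || lower_height >= upper_height)
    stop_("need 0 <= lower_height < upper_height")
  structure(list(lower_height = lower_height, upper_height = upper_height),
            class = "vegetation_params")
}

#' @rdname vegetation_params
#' @export
vegetation_params_tls <- function() vegetation_params(0.2, 50)

#' Detect high vegetation by normalized height
#'
#' @param x a normalized [point_cloud] or a CHM [raster_grid].
#' @param params a [vegetation_params].
#' @return A logical mask over points (cloud input) or cells (raster
#'   input); `TRUE` where `lower <= height <= upper` (inclusive).
#' @export
detect_high_vegetation <- function(x, params = vegetation_params()) {
  h <- if (inherits(x, "raster_grid")) x$values else x$points[, 3]
  m <- h >= params$lower_height & h <= params$upper_height
  m[is.na(m)] <- FALSE
  m
}
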