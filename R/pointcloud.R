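#' Point cloud container
#'
#' A lightweight container for LiDAR-style point clouds: an n x 3 matrix of
#' coordinates in metres plus an optional per-point classification label.
#'
#' @param points numeric matrix with columns x, y, z (metres).
#' @param class character vector of per-point labels, one of
#'   `"unclassified"`, `"ground"`, `"high_vegetation"`.
#' @param source `"ALS"`, `"TLS"` or `"synthetic"`.
#' @param nominal_density requested point density in points per square metre.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points,
                        class = rep("unclassified", nrow(points)),
                        source = "synthetic",
                        nominal_density = NA_real_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_("points must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop_("point coordinates must be finite")
  class <- as.character(class)
  if (length(class) != nrow(points))
    stop_("class labels must match the number of points")
  bad <- setdiff(unique(class), c("unclassified", "ground", "high_vegetation"))
  if (length(bad)) stop_("unknown class label(s): %s", paste(bad, collapse = ", "))
  if (!is.na(nominal_density) && nominal_density < 0)
    stop_("nominal_density must be >= 0")
  structure(list(points = points, class = class, source = source,
                 nominal_density = nominal_density),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, source %s, nominal density %s pts/m^2\n",
              nrow(x$points), x$source,
              format(x$nominal_density, digits = 6)))
  if (nrow(x$points)) {
    tab <- table(x$class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

subset_cloud <- function(cloud, keep) {
  point_cloud(cloud$points[keep, , drop = FALSE], cloud$class[keep],
              cloud$source, cloud$nominal_density)
}

#' Raster grid (DEM / CHM)
#'
#' Regular raster with a north-west origin and row-major cell order: row 1 is
#' the northernmost row, column 1 the westernmost column.  Cell (i, j) covers
#' x in `[x0 + (j-1) s, x0 + j s)` and y in `(y0 - i s, y0 - (i-1) s]`.
#'
#' @param origin numeric length 2, (x, y) of the north-west corner in metres.
#' @param cell_size cell edge length in metres, > 0.
#' @param values numeric matrix of cell values (NA allowed).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(origin, cell_size, values) {
  if (cell_size <= 0) stop_("cell_size must be > 0")
  values <- as.matrix(values)
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 n_rows = nrow(values), n_cols = ncol(values),
                 values = values),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells of %.3g m, NW origin (%.2f, %.2f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%.3f, %.3f], %d NA\n", min(v), max(v),
                             sum(!is.finite(x$values))))
  invisible(x)
}

## (x, y) -> (row, col); clamped into the grid
rg_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  list(row = clamp(row, 1L, grid$n_rows), col = clamp(col, 1L, grid$n_cols))
}

## cell-centre coordinates of every cell, row-major
rg_centers <- function(grid) {
  s <- grid$cell_size
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * s
  ys <- grid$origin[2] - (seq_len(grid$n_rows) - 0.5) * s
  list(x = xs, y = ys)
}

## value of the cell containing each (x, y)
rg_value_at <- function(grid, x, y) {
  rc <- rg_rowcol(grid, x, y)
  grid$values[cbind(rc$row, rc$col)]
}
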