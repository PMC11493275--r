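## Individual-tree crown delineation: marker-controlled watershed on a
## pit-filled, Gaussian-smoothed canopy height model.

#' Crown segmentation parameters
#'
#' Published defaults (ALS column): trunk/canopy step 2 m, growth step
#' 1 m, minimum 20 points per object.  The trunk/canopy step acts as the
#' treetop-marker minimum distance, the growth step as the flood-level
#' bin width of the watershed; for TLS use 0.15 m / 0.5 m / 40.
#'
#' @param chm_cell_size CHM cell size in m (0.25 ALS / 0.10 TLS).
#' @param chm_smoothing_sigma Gaussian smoothing sigma in cells.
#' @param local_max_min_distance minimum treetop separation in m
#'   (defaults to `trunk_step`).
#' @param trunk_step average step length of trunk/canopy in m.
#' @param growth_step flood-level bin width in m.
#' @param min_points_per_object minimum supporting points per crown.
#' @param min_height vegetation lower bound in m for segmentable cells.
#' @export
segmentation_params <- function(chm_cell_size = 0.25,
                                chm_smoothing_sigma = 1,
                                local_max_min_distance = NULL,
                                trunk_step = 2,
                                growth_step = 1,
                                min_points_per_object = 20L,
                                min_height = 2) {
  if (chm_cell_size <= 0) stop_("chm_cell_size must be > 0")
  if (min_points_per_object < 1L) stop_("min_points_per_object must be >= 1")
  structure(list(chm_cell_size = chm_cell_size,
                 chm_smoothing_sigma = chm_smoothing_sigma,
                 local_max_min_distance = local_max_min_distance %||% trunk_step,
                 trunk_step = trunk_step, growth_step = growth_step,
                 min_points_per_object = as.integer(min_points_per_object),
                 min_height = min_height),
            class = "segmentation_params")
}

#' @rdname segmentation_params
#' @export
segmentation_params_tls <- function() {
  segmentation_params(chm_cell_size = 0.10, trunk_step = 0.15,
                      growth_step = 0.5, min_points_per_object = 40L,
                      min_height = 0.2)
}

## 3x3 median pit fill: replaces a cell lower than all 8 neighbours by
## the neighbourhood median
pit_fill <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  nb <- array(NA_real_, c(nr, nc, 9L))
  for (k in seq_len(9L)) {
    di <- shifts$di[k]; dj <- shifts$dj[k]
    nb[, , k] <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  nbmin <- apply(nb[, , -5L, drop = FALSE], c(1, 2), max)  # max of neighbours
  pit <- m < apply(nb[, , -5L, drop = FALSE], c(1, 2), min) & is.finite(nbmin)
  if (any(pit)) {
    med <- apply(nb, c(1, 2), function(v) stats::median(v[is.finite(v)]))
    m[pit] <- med[pit]
  }
  m
}

## separable Gaussian smoothing with reflective borders
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  smooth1 <- function(mm) {           # along rows (dim 1)
    nr <- nrow(mm)
    idx <- outer(seq_len(nr), -r:r, "+")
    idx[idx < 1L] <- 1L - idx[idx < 1L] + 1L      # reflect
    idx[idx > nr] <- 2L * nr - idx[idx > nr]
    out <- matrix(0, nr, ncol(mm))
    for (t in seq_along(k)) out <- out + k[t] * mm[idx[, t], , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

## local maxima with minimum separation (greedy, highest first)
find_treetops <- function(values, min_dist_cells, min_height) {
  nr <- nrow(values); nc <- ncol(values)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- values
  is_max <- values >= min_height
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & values >= pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  cand <- which(is_max)
  if (!length(cand)) return(cbind(row = integer(0), col = integer(0)))
  ## merge connected plateaus (8-connectivity) into one candidate at the
  ## cell nearest the plateau centroid; smooth CHMs are unaffected
  comp <- integer(length(cand)); nid <- 0L
  cset <- logical(nr * nc); cset[cand] <- TRUE
  idx_of <- integer(nr * nc); idx_of[cand] <- seq_along(cand)
  for (s in seq_along(cand)) {
    if (comp[s] > 0L) next
    nid <- nid + 1L
    queue <- cand[s]; comp[s] <- nid
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      ci <- ((cell - 1L) %% nr) + 1L; cj <- ((cell - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- ci + di; nj <- cj + dj
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        ncell <- (nj - 1L) * nr + ni
        if (cset[ncell] && comp[idx_of[ncell]] == 0L) {
          comp[idx_of[ncell]] <- nid
          queue <- c(queue, ncell)
        }
      }
    }
  }
  cr_all <- ((cand - 1L) %% nr) + 1L
  cc_all <- ((cand - 1L) %/% nr) + 1L
  cand <- vapply(seq_len(nid), function(k) {
    ii <- comp == k
    mi <- mean(cr_all[ii]); mj <- mean(cc_all[ii])
    cand[ii][which.min((cr_all[ii] - mi)^2 + (cc_all[ii] - mj)^2)]
  }, integer(1))
  cr <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  ord <- order(values[cand], -cr, -cc, decreasing = TRUE)
  keep <- logical(length(cand))
  for (k in ord) {
    if (any(keep & (cr - cr[k])^2 + (cc - cc[k])^2 < min_dist_cells^2)) next
    keep[k] <- TRUE
  }
  cbind(row = cr[keep], col = cc[keep])
}

#' Segment individual crowns from a CHM
#'
#' Marker-controlled watershed: the CHM is pit-filled (3x3 median) and
#' Gaussian-smoothed, treetop markers are local maxima separated by at
#' least `local_max_min_distance`, and vegetation cells are flooded from
#' the markers in descending height order with flood levels quantized to
#' `growth_step`.  Segments supported by fewer than
#' `min_points_per_object` points (cloud points if `cloud` is given,
#' cells otherwise) are discarded.
#'
#' @param chm a [raster_grid] canopy height model.
#' @param params a [segmentation_params].
#' @param cloud optional normalized [point_cloud] used for the
#'   supporting-point count.
#' @return A `crown_segments` data frame (`segment_id`, `apex_x`,
#'   `apex_y`, `area_m2`, `R_m`, `H_m`, `n_cells`, `n_points`) with the
#'   label matrix in `attr(, "labels")`.
#' @export
segment_crowns <- function(chm, params = segmentation_params(), cloud = NULL) {
  v <- chm$values
  v[!is.finite(v)] <- 0
  nr <- nrow(v); nc <- ncol(v)
  s <- chm$cell_size
  vf <- pit_fill(v)
  vs <- gaussian_smooth(vf, params$chm_smoothing_sigma)
  veg <- vs >= params$min_height
  empty <- structure(data.frame(segment_id = integer(0), apex_x = numeric(0),
                                apex_y = numeric(0), area_m2 = numeric(0),
                                R_m = numeric(0), H_m = numeric(0),
                                n_cells = integer(0), n_points = integer(0)),
                     class = c("crown_segments", "data.frame"))
  attr(empty, "labels") <- matrix(0L, nr, nc)
  if (!any(veg)) return(empty)
  tops <- find_treetops(vs, max(1, params$local_max_min_distance / s),
                        params$min_height)
  if (!nrow(tops)) return(empty)
  labels <- matrix(0L, nr, nc)
  labels[tops] <- seq_len(nrow(tops))
  ## level-by-level flooding, levels binned by growth_step; within a
  ## level, unlabelled vegetation cells adjacent to a labelled cell take
  ## the label of their highest labelled neighbour (ties: lowest label),
  ## repeated to stability before descending to the next level
  step <- max(params$growth_step, 1e-6)
  levels <- sort(unique(floor(vs[veg] / step)), decreasing = TRUE)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  shift_mat <- function(m, d, fill) {
    out <- matrix(fill, nr, nc)
    si <- max(1L, 1L + d[1]):min(nr, nr + d[1])
    sj <- max(1L, 1L + d[2]):min(nc, nc + d[2])
    out[si - d[1], sj - d[2]] <- m[si, sj]
    out
  }
  for (L in levels) {
    in_level <- veg & floor(vs / step) == L
    repeat {
      cand <- in_level & labels == 0L
      if (!any(cand)) break
      best_h <- matrix(-Inf, nr, nc); best_lab <- matrix(0L, nr, nc)
      for (d in shifts) {
        nb_lab <- shift_mat(labels, d, 0L)
        nb_h <- shift_mat(vs, d, -Inf)
        nb_h[nb_lab == 0L] <- -Inf
        upd <- nb_h > best_h | (nb_h == best_h & nb_lab > 0L &
                                  (best_lab == 0L | nb_lab < best_lab))
        best_h[upd] <- nb_h[upd]
        best_lab[upd] <- nb_lab[upd]
      }
      take <- cand & best_lab > 0L
      if (!any(take)) break
      labels[take] <- best_lab[take]
    }
  }
  ## mop-up: vegetation cells whose flood path runs through a saddle can
  ## be reached only after lower levels fill; propagate until stable
  repeat {
    cand <- veg & labels == 0L
    if (!any(cand)) break
    best_h <- matrix(-Inf, nr, nc); best_lab <- matrix(0L, nr, nc)
    for (d in shifts) {
      nb_lab <- shift_mat(labels, d, 0L)
      nb_h <- shift_mat(vs, d, -Inf)
      nb_h[nb_lab == 0L] <- -Inf
      upd <- nb_h > best_h | (nb_h == best_h & nb_lab > 0L &
                                (best_lab == 0L | nb_lab < best_lab))
      best_h[upd] <- nb_h[upd]
      best_lab[upd] <- nb_lab[upd]
    }
    take <- cand & best_lab > 0L
    if (!any(take)) break
    labels[take] <- best_lab[take]
  }
  finalize_segments(chm, labels, veg, params, cloud, empty)
}

finalize_segments <- function(chm, labels, veg, params, cloud, empty) {
  v <- chm$values; v[!is.finite(v)] <- 0
  nr <- nrow(v); s <- chm$cell_size
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(empty)
  cc <- rg_centers(chm)
  ## supporting-point counts
  if (!is.null(cloud)) {
    rc <- rg_rowcol(chm, cloud$points[, 1], cloud$points[, 2])
    plab <- labels[cbind(rc$row, rc$col)]
    pt_count <- table(factor(plab[plab > 0L], levels = ids))
  }
  rows <- lapply(ids, function(id) {
    cells <- which(labels == id)
    np <- if (is.null(cloud)) length(cells)
          else as.integer(pt_count[as.character(id)])
    if (np < params$min_points_per_object) return(NULL)
    apex <- cells[which.max(v[cells])]
    ai <- ((apex - 1L) %% nr) + 1L
    aj <- ((apex - 1L) %/% nr) + 1L
    area <- length(cells) * s^2
    data.frame(segment_id = id, apex_x = cc$x[aj], apex_y = cc$y[ai],
               area_m2 = area, R_m = sqrt(area / pi),
               H_m = max(v[cells]), n_cells = length(cells),
               n_points = np)
  })
  keep_ids <- ids[!vapply(rows, is.null, logical(1))]
  labels[!(labels %in% keep_ids)] <- 0L
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$segment_id <- seq_len(nrow(out))
  labels <- matrix(match(labels, keep_ids, nomatch = 0L),
                   nrow(labels), ncol(labels))
  class(out) <- c("crown_segments", "data.frame")
  attr(out, "labels") <- labels
  out
}

#' Extract tree height per crown segment
#'
#' Height is the maximum normalized height over the segment footprint —
#' from the CHM by default, or from the points of a normalized cloud if
#' one is supplied.
#'
#' @param segments a `crown_segments` data frame with label raster.
#' @param chm the [raster_grid] the segments came from.
#' @param cloud optional normalized [point_cloud].
#' @return Numeric vector of heights (m), one per segment.
#' @export
extract_tree_height <- function(segments, chm, cloud = NULL) {
  labels <- attr(segments, "labels")
  if (is.null(labels)) stop_("segments lack their label raster")
  if (is.null(cloud)) {
    v <- chm$values; v[!is.finite(v)] <- 0
    vapply(segments$segment_id, function(id) max(v[labels == id]), numeric(1))
  } else {
    rc <- rg_rowcol(chm, cloud$points[, 1], cloud$points[, 2])
    plab <- labels[cbind(rc$row, rc$col)]
    vapply(segments$segment_id, function(id) {
      zz <- cloud$points[plab == id, 3]
      if (!length(zz)) return(NA_real_)
      max(zz)
    }, numeric(1))
  }
}
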