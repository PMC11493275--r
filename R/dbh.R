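## Stem-diameter estimation from TLS slices: algebraic circle fit with
## geometric refinement and robust trimming.

#' Algebraic (Kasa) circle fit
#'
#' Linear least squares on `x^2 + y^2 = 2 c_x x + 2 c_y y + r^2 - |c|^2`.
#'
#' @param x,y point coordinates.
#' @return list with `center` (length 2) and `radius`.
#' @export
circle_fit_algebraic <- function(x, y) {
  if (length(x) < 3L) stop_("circle fit needs >= 3 points")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop_("singular design in circle fit (collinear points?)"))
  cx <- sol[1]; cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  if (r2 <= 0) stop_("degenerate circle fit")
  list(center = c(cx, cy), radius = sqrt(r2))
}

#' Geometric circle fit (Gauss-Newton on orthogonal distances)
#'
#' Minimizes `sum (|p_i - c| - r)^2` starting from an algebraic fit.
#'
#' @param x,y point coordinates.
#' @param init optional list(center, radius) start value.
#' @param tol relative cost tolerance.
#' @param max_iter iteration cap.
#' @return list with `center`, `radius`, `rmse`, `converged`.
#' @export
circle_fit_geometric <- function(x, y, init = NULL, tol = 1e-12,
                                 max_iter = 100L) {
  init <- init %||% circle_fit_algebraic(x, y)
  p <- c(init$center, init$radius)
  cost <- function(p) {
    d <- sqrt((x - p[1])^2 + (y - p[2])^2)
    sum((d - p[3])^2)
  }
  f0 <- cost(p)
  lambda <- 1e-6
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dx <- x - p[1]; dy <- y - p[2]
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-12] <- 1e-12
    res <- d - p[3]
    J <- cbind(-dx / d, -dy / d, -1)
    g <- crossprod(J, res)
    Hm <- crossprod(J)
    step <- tryCatch(solve(Hm + lambda * diag(3), -g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    p_new <- p + as.numeric(step)
    f1 <- cost(p_new)
    if (f1 < f0) {
      if (abs(f0 - f1) <= tol * max(f0, 1e-300)) {
        p <- p_new; f0 <- f1; converged <- TRUE; break
      }
      p <- p_new; f0 <- f1; lambda <- max(lambda / 10, 1e-12)
    } else lambda <- lambda * 10
    if (lambda > 1e12) { converged <- TRUE; break }   # stuck at optimum
  }
  list(center = p[1:2], radius = p[3],
       rmse = sqrt(f0 / length(x)), converged = converged)
}

#' Circumcircle of three points (closed form)
#'
#' Independent oracle for the circle fitters: the unique circle through
#' three non-collinear points.
#'
#' @param p1,p2,p3 length-2 numeric points.
#' @return list with `center` and `radius`.
#' @export
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) stop_("collinear points have no circumcircle")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Estimate DBH from a TLS stem slice
#'
#' Takes the normalized-height slice `slice_center +/- slice_halfwidth`
#' within `search_radius` of the seed position, fits a circle
#' (algebraic then geometric), trims points farther than 3 MAD from the
#' fitted circle, refits once, and reports the diameter in cm.
#'
#' @param cloud a height-normalized [point_cloud] (TLS).
#' @param seed_xy length-2 numeric, approximate stem position.
#' @param slice_center slice height in m (breast height, 1.3).
#' @param slice_halfwidth slice half-width in m.
#' @param search_radius horizontal search radius around the seed in m.
#' @param min_points minimum slice points required.
#' @return list with `ok`, `dbh_cm`, `center`, `n_points`, `rmse_m`; if
#'   too few points, `ok = FALSE` and `dbh_cm = NA` (tree flagged, not
#'   an error).
#' @export
estimate_dbh <- function(cloud, seed_xy, slice_center = 1.3,
                         slice_halfwidth = 0.05, search_radius = 1.0,
                         min_points = 10L) {
  z <- cloud$points[, 3]
  sel <- abs(z - slice_center) <= slice_halfwidth &
    (cloud$points[, 1] - seed_xy[1])^2 +
    (cloud$points[, 2] - seed_xy[2])^2 <= search_radius^2
  n <- sum(sel)
  if (n < max(3L, min_points))
    return(list(ok = FALSE, dbh_cm = NA_real_, center = c(NA_real_, NA_real_),
                n_points = n, rmse_m = NA_real_))
  x <- cloud$points[sel, 1]; y <- cloud$points[sel, 2]
  ## robust pre-trim: gross outliers (branches, neighbouring stems) have
  ## quadratic leverage on the algebraic fit, so screen them first
  ## against a median-centre / median-radius circle
  cx0 <- stats::median(x); cy0 <- stats::median(y)
  d0 <- sqrt((x - cx0)^2 + (y - cy0)^2)
  r0 <- stats::median(d0)
  mad0 <- stats::mad(d0 - r0, center = 0)
  if (mad0 > 1e-12) {
    pre <- abs(d0 - r0) <= 5 * mad0
    if (sum(pre) >= max(3L, min_points)) { x <- x[pre]; y <- y[pre] }
  }
  fit <- circle_fit_geometric(x, y)
  res <- abs(sqrt((x - fit$center[1])^2 + (y - fit$center[2])^2) - fit$radius)
  mad <- stats::mad(res, center = 0)
  if (mad > 1e-12) {
    keep <- res <= 3 * mad
    if (sum(keep) >= max(3L, min_points) && any(!keep))
      fit <- circle_fit_geometric(x[keep], y[keep],
                                  init = list(center = fit$center,
                                              radius = fit$radius))
  }
  list(ok = TRUE, dbh_cm = 200 * fit$radius, center = fit$center,
       n_points = n, rmse_m = fit$rmse)
}
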