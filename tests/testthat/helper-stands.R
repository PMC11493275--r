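## Shared fixtures, all built in code.

## a small stand of well-separated trees on a rectangular grid
make_separated_stand <- function(n_x = 3, n_y = 2, spacing = 9,
                                 species = "larch",
                                 H = NULL, DBH = 15, R = 2) {
  n <- n_x * n_y
  g <- expand.grid(x = spacing * (seq_len(n_x) - 0.5),
                   y = spacing * (seq_len(n_y) - 0.5))
  if (is.null(H)) H <- seq(9, 14, length.out = n)
  data.frame(
    tree_id = seq_len(n), plot_id = 1L, species = species,
    x = g$x, y = g$y,
    H_m = H, DBH_cm = rep_len(DBH, n), R_m = rep_len(R, n),
    W_ref_kg = NA_real_, source = "synthetic")
}

## points on a vertical cylinder surface around (cx, cy), for DBH tests
make_cylinder_slice <- function(radius = 0.10, n = 200, noise_sd = 0,
                                arc = 2 * pi, center = c(10, 10),
                                z_range = c(1.26, 1.34), seed = 1) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); force(expr)
  }
  withr_seed(seed, {
    th <- stats::runif(n, 0, arc)
    r <- radius + stats::rnorm(n, 0, noise_sd)
    z <- stats::runif(n, z_range[1], z_range[2])
    point_cloud(cbind(center[1] + r * cos(th), center[2] + r * sin(th), z),
                rep("high_vegetation", n), source = "TLS")
  })
}

## flat-ground cloud plus one conical crown, noise-free, exact labels
make_plane_plus_cone <- function(ground_n = 2000, H = 12, R = 2,
                                 extent = 20, seed = 2) {
  set.seed(seed)
  gx <- runif(ground_n, 0, extent); gy <- runif(ground_n, 0, extent)
  cb <- 0.35 * H
  n_c <- 400
  u <- runif(n_c); th <- runif(n_c, 0, 2 * pi)
  r <- R * sqrt(u)
  cz <- cb + (H - cb) * (1 - r / R)
  pts <- rbind(cbind(gx, gy, 0),
               cbind(extent / 2 + r * cos(th), extent / 2 + r * sin(th), cz))
  point_cloud(pts, c(rep("ground", ground_n), rep("high_vegetation", n_c)))
}

## brute-force optimal assignment oracle (<= ~6 x 6), maximizing match
## count then minimizing total distance
brute_force_match <- function(d, threshold) {
  na <- nrow(d); nt <- ncol(d)
  best <- list(card = -1L, cost = Inf)
  ## enumerate injective partial maps rows -> cols via recursion
  rec <- function(i, used, pairs) {
    if (i > na) {
      card <- nrow(pairs)
      cost <- if (card) sum(d[pairs]) else 0
      if (card > best$card || (card == best$card && cost < best$cost - 1e-12))
        best <<- list(card = card, cost = cost, pairs = pairs)
      return(invisible())
    }
    rec(i + 1L, used, pairs)                      # leave row i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && d[i, j] <= threshold)
        rec(i + 1L, replace(used, j, TRUE), rbind(pairs, c(i, j)))
    }
  }
  rec(1L, rep(FALSE, nt), matrix(integer(0), 0, 2))
  best
}
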