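#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

## Nearest-neighbour horizontal distances from each query (x,y) to a
## reference set, via grid buckets (pure R, adequate at package scales).
nn_dist_xy <- function(qx, qy, rx, ry, cell = 1) {
  nq <- length(qx)
  if (nq == 0L) return(numeric(0))
  if (length(rx) == 0L) return(rep(Inf, nq))
  x0 <- min(rx, qx); y0 <- min(ry, qy)
  ri <- floor((rx - x0) / cell); rj <- floor((ry - y0) / cell)
  key <- paste(ri, rj)
  buckets <- split(seq_along(rx), key)
  qi <- floor((qx - x0) / cell); qj <- floor((qy - y0) / cell)
  out <- numeric(nq)
  max_ring <- ceiling(max(diff(range(c(rx, qx))), diff(range(c(ry, qy)))) / cell) + 1L
  for (k in seq_len(nq)) {
    ring <- 0L; best <- Inf
    repeat {
      ## cells at Chebyshev cell distance == ring
      if (ring == 0L) {
        keys <- paste(qi[k], qj[k])
      } else {
        ii <- (qi[k] - ring):(qi[k] + ring)
        keys <- c(paste(ii, qj[k] - ring), paste(ii, qj[k] + ring),
                  paste(qi[k] - ring, (qj[k] - ring + 1L):(qj[k] + ring - 1L)),
                  paste(qi[k] + ring, (qj[k] - ring + 1L):(qj[k] + ring - 1L)))
      }
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (!is.null(cand) && length(cand)) {
        d2 <- (rx[cand] - qx[k])^2 + (ry[cand] - qy[k])^2
        best <- min(best, min(d2))
      }
      ## a point in ring r is at Euclidean distance >= (r - 1) * cell,
      ## so stop once that bound exceeds the best distance found
      ring <- ring + 1L
      if ((is.finite(best) && (ring - 1L) * cell >= sqrt(best)) || ring > max_ring)
        break
    }
    out[k] <- sqrt(best)
  }
  out
}

## Approximate horizontal distance from each query to the nearest
## reference point via a chamfer distance transform on a `cell`-sized
## grid, capped at `cap` metres (values beyond the cap saturate).
grid_dist_to_set <- function(qx, qy, rx, ry, cell = 1, cap = 6) {
  if (!length(qx)) return(numeric(0))
  x0 <- min(rx, qx); y0 <- min(ry, qy)
  nc <- floor((max(rx, qx) - x0) / cell) + 1L
  nr <- floor((max(ry, qy) - y0) / cell) + 1L
  D <- matrix(Inf, nr, nc)
  D[cbind(floor((ry - y0) / cell) + 1L, floor((rx - x0) / cell) + 1L)] <- 0
  shifts <- list(c(-1L, 0L, 1), c(1L, 0L, 1), c(0L, -1L, 1), c(0L, 1L, 1),
                 c(-1L, -1L, sqrt(2)), c(-1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)), c(1L, 1L, sqrt(2)))
  n_pass <- ceiling(cap / cell) + 1L
  for (p in seq_len(n_pass)) {
    D_old <- D
    for (s in shifts) {
      si <- max(1L, 1L + s[1]):min(nr, nr + s[1])
      sj <- max(1L, 1L + s[2]):min(nc, nc + s[2])
      block <- D[si, sj, drop = FALSE] + s[3] * cell
      ti <- si - s[1]; tj <- sj - s[2]
      cur <- D[ti, tj, drop = FALSE]
      D[ti, tj] <- pmin(cur, block)
    }
    if (identical(D, D_old)) break
  }
  D[!is.finite(D)] <- cap + cell
  pmin(D[cbind(floor((qy - y0) / cell) + 1L, floor((qx - x0) / cell) + 1L)],
       cap + cell)
}
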