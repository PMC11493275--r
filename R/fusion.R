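## ALS-TLS fusion: one-to-one tree matching by trunk/apex proximity.

## O(n^3) Hungarian algorithm (shortest augmenting path with dual
## potentials) on a square cost matrix; deterministic, scans columns in
## index order so cost ties resolve to the lower index.
hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(INF, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        jj <- j + 1L
        if (!used[jj]) {
          cur <- cost[i0, j] - u[i0 + 0] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in seq_len(n + 1)) {
        if (used[jj]) { u[p[jj]] <- u[p[jj]] + delta; v[jj] <- v[jj] - delta }
        else minv[jj] <- minv[jj] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  ## p[j+1] = row assigned to column j
  assign_row <- integer(n)
  assign_row[seq_len(n)] <- p[2:(n + 1)]
  match_of_row <- integer(n)
  match_of_row[assign_row] <- seq_len(n)
  match_of_row
}

## minimum-cost one-to-one assignment allowing unmatched; forbidden
## pairs get cost M, dummies cost M, so cardinality is maximized first,
## then total distance minimized
assignment_with_threshold <- function(d, threshold) {
  na <- nrow(d); nt <- ncol(d)
  n <- na + nt
  M <- (sum(d[is.finite(d)]) + threshold + 1) * 4
  cost <- matrix(M, n, n)
  dd <- d
  dd[dd > threshold] <- M * 2
  cost[seq_len(na), seq_len(nt)] <- dd
  cost[(na + 1):n, (nt + 1):n] <- 0          # dummy-dummy free
  m <- hungarian(cost)                        # m[row] = column
  pairs <- cbind(row = seq_len(na), col = m[seq_len(na)])
  ok <- pairs[, "col"] <= nt
  ok[ok] <- d[pairs[ok, , drop = FALSE]] <= threshold
  pairs[ok, , drop = FALSE]
}

#' Match ALS and TLS tree lists by position
#'
#' One-to-one matching that minimizes total planimetric distance over
#' pairs within `max_distance` (optimal assignment, maximum cardinality
#' first).  The fused record takes H and R from the ALS tree, DBH from
#' the TLS tree, and the TLS position as the stem centre.  Unmatched
#' trees on either side are reported, never dropped.
#'
#' @param als_trees,tls_trees `tree_records` data frames with `x`, `y`.
#' @param max_distance matching threshold in m.
#' @return list with `matches` (`als_tree_id`, `tls_tree_id`,
#'   `distance`), `fused` (a `tree_records` data frame with
#'   `source = "fused"`), `unmatched_als`, `unmatched_tls` (tree ids).
#' @export
match_trees <- function(als_trees, tls_trees, max_distance = 1.0) {
  if (!nrow(als_trees) || !nrow(tls_trees))
    stop_("both tree lists must be non-empty")
  als_trees <- als_trees[order(als_trees$tree_id), , drop = FALSE]
  tls_trees <- tls_trees[order(tls_trees$tree_id), , drop = FALSE]
  d <- sqrt(outer(als_trees$x, tls_trees$x, "-")^2 +
              outer(als_trees$y, tls_trees$y, "-")^2)
  allowed <- d <= max_distance
  ## connected components of the bipartite "allowed" graph keep the
  ## Hungarian solves tiny
  na <- nrow(als_trees); nt <- nrow(tls_trees)
  comp_a <- rep(0L, na); comp_t <- rep(0L, nt); ncomp <- 0L
  for (i in seq_len(na)) {
    if (comp_a[i] > 0L || !any(allowed[i, ])) next
    ncomp <- ncomp + 1L
    qa <- i
    while (length(qa)) {
      comp_a[qa] <- ncomp
      qt <- which(colSums(allowed[qa, , drop = FALSE]) > 0 & comp_t == 0L)
      if (!length(qt)) break
      comp_t[qt] <- ncomp
      qa <- which(rowSums(allowed[, qt, drop = FALSE]) > 0 & comp_a == 0L)
    }
  }
  pairs <- NULL
  for (k in seq_len(ncomp)) {
    ia <- which(comp_a == k); it <- which(comp_t == k)
    sub <- assignment_with_threshold(d[ia, it, drop = FALSE], max_distance)
    if (nrow(sub))
      pairs <- rbind(pairs, cbind(ia[sub[, "row"]], it[sub[, "col"]]))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  ord <- order(als_trees$tree_id[pairs[, 1]])
  pairs <- pairs[ord, , drop = FALSE]
  matches <- data.frame(
    als_tree_id = als_trees$tree_id[pairs[, 1]],
    tls_tree_id = tls_trees$tree_id[pairs[, 2]],
    distance = d[pairs])
  fused <- if (nrow(pairs)) {
    a <- als_trees[pairs[, 1], , drop = FALSE]
    t <- tls_trees[pairs[, 2], , drop = FALSE]
    as_tree_records(data.frame(
      tree_id = a$tree_id, plot_id = a$plot_id, species = a$species,
      x = t$x, y = t$y, H_m = a$H_m, DBH_cm = t$DBH_cm, R_m = a$R_m,
      W_ref_kg = NA_real_, source = "fused"))
  } else as_tree_records(als_trees[0, , drop = FALSE])
  list(matches = matches, fused = fused,
       unmatched_als = setdiff(als_trees$tree_id, matches$als_tree_id),
       unmatched_tls = setdiff(tls_trees$tree_id, matches$tls_tree_id))
}
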