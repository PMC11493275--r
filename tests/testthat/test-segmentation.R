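## rasterize a stand of ideal cone crowns straight into a CHM
cone_chm <- function(trees, cell = 0.25, extent = 30, base_frac = 0) {
  n <- ceiling(extent / cell)
  xs <- (seq_len(n) - 0.5) * cell
  chm <- matrix(0, n, n)
  ys <- rev(xs)                                 # row 1 = north
  for (k in seq_len(nrow(trees))) {
    dx <- outer(rep(1, n), xs) - trees$x[k]
    dy <- outer(ys, rep(1, n)) - trees$y[k]
    r <- sqrt(dx^2 + dy^2)
    cb <- base_frac * trees$H_m[k]
    h <- ifelse(r <= trees$R_m[k],
                cb + (trees$H_m[k] - cb) * (1 - r / trees$R_m[k]), 0)
    chm <- pmax(chm, h)
  }
  raster_grid(origin = c(0, extent), cell_size = cell, values = chm)
}

test_that("two separated cones yield two segments with apexes at the stems", {
  trees <- data.frame(x = c(10, 18), y = c(15, 15), H_m = c(12, 14), R_m = 2.5)
  chm <- cone_chm(trees)
  segs <- segment_crowns(chm, segmentation_params())
  expect_equal(nrow(segs), 2L)
  segs <- segs[order(segs$apex_x), ]
  expect_lt(max(abs(segs$apex_x - trees$x)), chm$cell_size + 1e-9)
  expect_lt(max(abs(segs$apex_y - trees$y)), chm$cell_size + 1e-9)
  ## segments are disjoint and confined to vegetation cells
  labels <- attr(segment_crowns(chm), "labels")
  expect_lte(sum(labels > 0) * chm$cell_size^2,
             sum(chm$values >= 2) * chm$cell_size^2 + 1e-9)
})

test_that("a single crown's equivalent radius matches truth within one cell", {
  trees <- data.frame(x = 15, y = 15, H_m = 12, R_m = 2.4)
  chm <- cone_chm(trees, base_frac = 0.35)  # crown base above min height
  segs <- segment_crowns(chm)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$R_m, 2.4, tolerance = chm$cell_size / 2.4)
  ## identity R = sqrt(area / pi) holds exactly
  expect_equal(segs$R_m, sqrt(segs$area_m2 / pi), tolerance = 1e-12)
})

test_that("equivalent radius of a rasterized disc is within one cell of truth", {
  cell <- 0.25
  n <- 120
  xs <- (seq_len(n) - 0.5) * cell
  d <- sqrt(outer((xs - 15)^2, rep(1, n)) + outer(rep(1, n), (xs - 15)^2))
  chm <- raster_grid(c(0, n * cell), cell,
                     matrix(ifelse(d <= 2, 8, 0), n, n))
  segs <- segment_crowns(chm, segmentation_params(chm_smoothing_sigma = 0))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$R_m, 2, tolerance = cell / 2)
})

test_that("raising the minimum object size only removes segments", {
  trees <- data.frame(x = c(8, 15, 22), y = c(15, 15, 15),
                      H_m = c(10, 12, 11), R_m = c(1.2, 2.5, 1.8))
  chm <- cone_chm(trees)
  counts <- vapply(c(1L, 50L, 200L, 400L, 2000L), function(mp) {
    nrow(segment_crowns(chm, segmentation_params(min_points_per_object = mp)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_equal(counts[1], 3L)
})

test_that("equivalent radius is stable under translation and rotation", {
  trees <- data.frame(x = 13, y = 16, H_m = 12, R_m = 2.2)
  chm1 <- cone_chm(trees)
  r1 <- segment_crowns(chm1)$R_m
  ## translate the stand by a non-integer cell offset
  trees2 <- transform(trees, x = x + 0.37, y = y - 0.58)
  r2 <- segment_crowns(cone_chm(trees2))$R_m
  ## rotate the stand 90 degrees about the grid centre
  trees3 <- data.frame(x = 30 - trees$y, y = trees$x, H_m = 12, R_m = 2.2)
  r3 <- segment_crowns(cone_chm(trees3))$R_m
  expect_lt(max(abs(c(r2, r3) - r1)), chm1$cell_size)
})

test_that("tree height extraction returns the segment maximum", {
  trees <- data.frame(x = 15, y = 15, H_m = 15, R_m = 2.5)
  chm <- cone_chm(trees)
  segs <- segment_crowns(chm)
  expect_equal(extract_tree_height(segs, chm), 15, tolerance = 0.15)
  ## constant-height segment: H equals that value
  flat <- raster_grid(c(0, 10), 0.5, matrix(c(rep(0, 200), rep(7, 200)), 20, 20))
  s2 <- segment_crowns(flat, segmentation_params(chm_smoothing_sigma = 0,
                                                 min_points_per_object = 5L))
  expect_true(all(abs(extract_tree_height(s2, flat) - 7) < 1e-9))
  expect_error(extract_tree_height(data.frame(segment_id = 1), chm), "label")
})

test_that("an empty or sub-threshold CHM yields no segments", {
  g <- raster_grid(c(0, 5), 0.5, matrix(0.5, 10, 10))
  expect_equal(nrow(segment_crowns(g)), 0L)
})
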