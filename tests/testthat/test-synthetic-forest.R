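test_that("default four-plot configuration reproduces the study population", {
  cfg <- forest_config(seed = 11)
  tr <- sample_tree_population(cfg)
  expect_equal(nrow(tr), 625)
  expect_equal(as.integer(table(tr$plot_id)), c(126L, 127L, 290L, 82L))
  ## clipping invariant: every attribute inside its plot's range
  prof <- default_species_profiles()
  for (k in 1:4) {
    p <- prof[[k]]; d <- tr[tr$plot_id == k, ]
    expect_true(all(d$H_m >= p$H_range[1] & d$H_m <= p$H_range[2]))
    expect_true(all(d$DBH_cm >= p$DBH_range[1] & d$DBH_cm <= p$DBH_range[2]))
    expect_true(all(d$R_m >= p$R_range[1] & d$R_m <= p$R_range[2]))
    expect_equal(unique(d$species), p$species_id)
  }
  ## min spacing honoured within each plot
  for (k in 1:4) {
    d <- tr[tr$plot_id == k, ]
    expect_gte(min(dist(cbind(d$x, d$y))), cfg$min_spacing)
  }
})

test_that("a single draw respects clipping and determinism", {
  pr <- species_profile("ash", c(7, 12), c(7, 16), c(1, 2.7))
  cfg <- forest_config(list(plot_spec(1L, pr, c(10, 10), 1L)), seed = 3)
  tr <- sample_tree_population(cfg)
  expect_equal(nrow(tr), 1L)
  expect_true(tr$H_m >= 7 && tr$H_m <= 12)
  expect_true(tr$DBH_cm >= 7 && tr$DBH_cm <= 16)
  expect_true(tr$R_m >= 1 && tr$R_m <= 2.7)
  expect_identical(tr, sample_tree_population(cfg))
})

test_that("zero noise makes H and R exact power laws of DBH", {
  pr <- species_profile("larch", c(8, 16), c(12, 19), c(1.6, 3.3),
                        noise_sd_H = 0, noise_sd_R = 0)
  cfg <- forest_config(list(plot_spec(1L, pr, c(40, 40), 60L)), seed = 9)
  tr <- sample_tree_population(cfg)
  ## independent recomputation of the calibrated power law:
  ## exponent/scale from the range endpoints via logs
  eH <- (log(16) - log(8)) / (log(19) - log(12))
  sH <- 8 / 12^eH
  H_expect <- pmin(pmax(sH * exp(eH * log(tr$DBH_cm)), 8), 16)
  expect_equal(tr$H_m, H_expect, tolerance = 1e-12)
  eR <- (log(3.3) - log(1.6)) / (log(19) - log(12))
  sR <- 1.6 / 12^eR
  R_expect <- pmin(pmax(sR * exp(eR * log(tr$DBH_cm)), 1.6), 3.3)
  expect_equal(tr$R_m, R_expect, tolerance = 1e-12)
})

test_that("infeasible or unplaceable configurations error with the plot named", {
  pr <- species_profile("larch", c(8, 16), c(12, 19), c(1.6, 3.3))
  expect_error(forest_config(list(plot_spec(7L, pr, c(3, 3), 50L)),
                             min_spacing = 2),
               "plot 7")
  ## passes the area feasibility check but placement is starved of attempts
  cfg <- forest_config(list(plot_spec(2L, pr, c(6, 6), 20L)),
                       min_spacing = 1, max_attempts = 2L)
  expect_error(sample_tree_population(cfg), "plot 2")
})

test_that("profile validation rejects bad ranges and noise", {
  expect_error(species_profile("larch", c(16, 8), c(12, 19), c(1, 3)), "min < max")
  expect_error(species_profile("larch", c(8, 16), c(12, 19), c(1, 3),
                               noise_sd_H = -1), "noise")
  expect_error(species_profile("oak", c(8, 16), c(12, 19), c(1, 3)))
})

test_that("rendered clouds are reproducible and respect the density budget", {
  trees <- make_separated_stand(n_x = 1, n_y = 1, H = 10)
  a <- render_point_cloud(trees, "ALS", density = 2281.92,
                          extent = c(0, 10, 0, 10), seed = 4)
  b <- render_point_cloud(trees, "ALS", density = 2281.92,
                          extent = c(0, 10, 0, 10), seed = 4)
  expect_identical(a$points, b$points)
  expect_identical(a$class, b$class)
  ## density 2281.92 pts/m^2 over 10 x 10 m -> about 228192 points (10 %)
  expect_lt(abs(nrow(a$points) - 228192) / 228192, 0.10)
})

test_that("a single conifer's apex bounds the maximum z", {
  trees <- make_separated_stand(n_x = 1, n_y = 1, H = 15)
  sd_z <- 0.05
  cl <- render_point_cloud(trees, "ALS", density = 100, terrain = 0,
                           noise_sd_z = sd_z, extent = c(0, 9, 0, 9), seed = 8)
  zmax <- max(cl$points[, 3])
  expect_lte(zmax, 15)
  expect_gte(zmax, 15 - 3 * sd_z)
})

test_that("TLS stem returns lie on the DBH circle in the breast-height slice", {
  trees <- make_separated_stand(n_x = 1, n_y = 1, H = 12, DBH = 20)
  cl <- render_point_cloud(trees, "TLS", density = 300, noise_sd_z = 0,
                           extent = c(0, 9, 0, 9), seed = 5)
  z <- cl$points[, 3]
  sl <- cl$class == "high_vegetation" & abs(z - 1.3) <= 0.05 &
    sqrt((cl$points[, 1] - trees$x)^2 + (cl$points[, 2] - trees$y)^2) < 0.5
  expect_gte(sum(sl), 30)
  r <- sqrt((cl$points[sl, 1] - trees$x)^2 + (cl$points[sl, 2] - trees$y)^2)
  expect_equal(r, rep(0.10, sum(sl)), tolerance = 1e-9)
})

test_that("an empty tree list renders only ground returns", {
  cl <- render_point_cloud(make_separated_stand()[0, ], "ALS", density = 50,
                           extent = c(0, 5, 0, 5), seed = 1)
  expect_true(all(cl$class == "ground"))
  expect_error(render_point_cloud(make_separated_stand(), "ALS", density = -5),
               "density")
  expect_error(render_point_cloud(make_separated_stand(), "ALS", density = 5,
                                  extent = c(0, 0, 0, 5)), "extent")
})
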