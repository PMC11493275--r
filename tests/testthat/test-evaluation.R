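test_that("the seven scenarios map to their plot sets", {
  sets <- list(1L, 2L, c(1L, 2L), 3L, 4L, c(3L, 4L), 1:4)
  for (id in 1:7) expect_equal(scenario_spec(id)$plots, sets[[id]])
  expect_error(scenario_spec(8), "1-7")
})

test_that("scenario assembly concatenates plots in stable order", {
  tr <- sample_tree_population(forest_config(seed = 6))
  expect_equal(nrow(assemble_scenario(tr, 3)), 253L)   # 126 + 127
  expect_equal(nrow(assemble_scenario(tr, 7)), 625L)
  one <- assemble_scenario(tr, 2)
  expect_equal(one$tree_id, sort(tr$tree_id[tr$plot_id == 2]))
  s6 <- assemble_scenario(tr, 6)
  expect_true(!is.unsorted(s6$plot_id))
})

test_that("the 70/30 split is sized by banker's rounding and reproducible", {
  d <- data.frame(i = 1:126)
  sp <- split_train_test(d, 0.7, seed = 12)
  expect_equal(nrow(sp$train), 88L)                    # round(88.2)
  expect_equal(nrow(sp$test), 38L)
  d10 <- data.frame(i = 1:10)
  sp10 <- split_train_test(d10, 0.7, seed = 1)
  expect_equal(c(nrow(sp10$train), nrow(sp10$test)), c(7L, 3L))
  ## disjoint, exhaustive, deterministic
  expect_setequal(c(sp$train$i, sp$test$i), 1:126)
  sp2 <- split_train_test(d, 0.7, seed = 12)
  expect_identical(sp$train$i, sp2$train$i)
  expect_error(split_train_test(d, 1.2), "fraction")
})

test_that("the full matrix has 63 flagged-and-ranked rows and is deterministic", {
  tr <- add_reference_agb(sample_tree_population(forest_config(seed = 2)))
  res <- run_model_matrix(tr, run_config(seed = 5))
  expect_equal(nrow(res), 63L)
  expect_true(all(res$converged))
  expect_true(all(res$n_train + res$n_test ==
                    c(126, 127, 253, 290, 82, 372, 625)[res$scenario]))
  ## per-scenario ranks cover 1..9
  for (sc in 1:7)
    expect_setequal(res$rank_test[res$scenario == sc], 1:9)
  res2 <- run_model_matrix(tr, run_config(seed = 5))
  expect_identical(res, res2)
  ## restricted model list
  expect_equal(nrow(run_model_matrix(tr, run_config(models = "Eq9"))), 7L)
})

test_that("data generated by Eq9 itself fits perfectly in every scenario", {
  tr <- sample_tree_population(forest_config(seed = 3))
  tr$W_ref_kg <- model_predict("Eq9", c(a = 0.8, b = 4, c = 10),
                               tr$H_m, tr$R_m)
  res <- run_model_matrix(tr, run_config(models = "Eq9", seed = 1))
  expect_true(all(res$r2_train > 1 - 1e-10))
  expect_true(all(res$r2_test > 1 - 1e-10))
  expect_true(all(res$rmse_test < 1e-5))
})

test_that("held-out rows never leak into training coefficients", {
  tr <- add_reference_agb(sample_tree_population(forest_config(seed = 8)))
  cfg <- run_config(seed = 33, scenarios = 3, models = c("Eq1", "Eq9"))
  base <- run_model_matrix(tr, cfg)
  ## permute the reference AGB of the test rows only
  ds <- assemble_scenario(tr, 3)
  sp <- split_train_test(ds, 0.7, seed = 33)
  perm <- tr
  ids <- sp$test$tree_id
  set.seed(1)
  perm$W_ref_kg[match(ids, perm$tree_id)] <-
    sample(perm$W_ref_kg[match(ids, perm$tree_id)])
  mod <- run_model_matrix(perm, cfg)
  expect_identical(base[c("a", "b", "c")], mod[c("a", "b", "c")])
  expect_false(isTRUE(all.equal(base$r2_test, mod$r2_test)))
})

test_that("replicates aggregate to mean and sd per scenario-model", {
  tr <- add_reference_agb(sample_tree_population(forest_config(seed = 4)))
  res <- run_model_matrix(tr, run_config(scenarios = c(1, 5),
                                         models = c("Eq1", "Eq9"),
                                         replicates = 3))
  expect_equal(nrow(res), 12L)
  agg <- summarize_replicates(res)
  expect_equal(nrow(agg), 4L)
  expect_true(all(c("r2_test_mean", "r2_test_sd") %in% names(agg)))
  expect_true(all(agg$r2_test_sd >= 0, na.rm = TRUE))
})

test_that("results write as CSV, JSON and a ranked text summary", {
  tr <- add_reference_agb(sample_tree_population(forest_config(seed = 4)))
  res <- run_model_matrix(tr, run_config(scenarios = 1, models = c("Eq1", "Eq9")))
  dir <- withr::local_tempdir()
  write_fit_results(res, dir)
  expect_true(file.exists(file.path(dir, "fit_results.csv")))
  back <- read.csv(file.path(dir, "fit_results.csv"))
  expect_equal(nrow(back), 2L)
  js <- jsonlite::read_json(file.path(dir, "fit_results.json"))
  expect_length(js, 2L)
  expect_true(any(grepl("Scenario 1", readLines(file.path(dir, "fit_summary.txt")))))
})
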