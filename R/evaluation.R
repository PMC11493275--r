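## Scenario assembly, train/test splitting, and the 7 x 9 model matrix.

.scenario_plots <- list(`1` = 1L, `2` = 2L, `3` = c(1L, 2L), `4` = 3L,
                        `5` = 4L, `6` = c(3L, 4L), `7` = 1:4)
.scenario_desc <- c(
  "Shorter coniferous forest (plot 1)",
  "Taller coniferous forest (plot 2)",
  "Mixed tall and short coniferous forest (plots 1+2)",
  "Taller broadleaf forest (plot 3)",
  "Shorter broadleaf forest (plot 4)",
  "Mixed tall and short broadleaf forest (plots 3+4)",
  "Mixed coniferous-broadleaf forest (plots 1+2+3+4)")

#' Species-mixture scenarios
#'
#' The seven plot combinations: single plots (1, 2, 4, 5), within-type
#' mixtures (3: plots 1+2; 6: plots 3+4) and the full pool (7).
#'
#' @param id scenario id, 1-7.
#' @return list with `scenario_id`, `plots`, `description`.
#' @export
scenario_spec <- function(id) {
  id <- as.integer(id)
  if (!id %in% 1:7) stop_("scenario id must be 1-7")
  list(scenario_id = id, plots = .scenario_plots[[as.character(id)]],
       description = .scenario_desc[id])
}

#' Assemble a scenario's tree table
#'
#' Concatenates the named plots' trees in stable `(plot_id, tree_id)`
#' order.
#'
#' @param trees a `tree_records` data frame covering all plots.
#' @param scenario a [scenario_spec()] or a scenario id.
#' @export
assemble_scenario <- function(trees, scenario) {
  if (is.numeric(scenario)) scenario <- scenario_spec(scenario)
  sub <- trees[trees$plot_id %in% scenario$plots, , drop = FALSE]
  sub <- sub[order(sub$plot_id, sub$tree_id), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Random train/test split
#'
#' `round(fraction * n)` rows (banker's rounding, platform-stable) go to
#' the training set; the split is disjoint, exhaustive and reproducible
#' by seed.
#'
#' @param data a data frame.
#' @param fraction training fraction in (0, 1); default 0.7.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` data frames.
#' @export
split_train_test <- function(data, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_("fraction must be in (0, 1)")
  n <- nrow(data)
  n_train <- as.integer(round(fraction * n))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Run configuration for the model matrix
#'
#' @param fraction training fraction (default 0.7).
#' @param seed split seed shared across all fits of a run.
#' @param models model codes to run (default all nine).
#' @param scenarios scenario ids (default 1-7).
#' @param clip_negative clip negative predictions to 0 before scoring
#'   (off by default; Eq6/7/9 can predict below zero).
#' @param replicates number of split seeds (seed, seed+1, ...).
#' @export
run_config <- function(fraction = 0.7, seed = 1L, models = model_codes(),
                       scenarios = 1:7, clip_negative = FALSE,
                       replicates = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_("fraction must be in (0, 1)")
  structure(list(fraction = fraction, seed = as.integer(seed),
                 models = models, scenarios = as.integer(scenarios),
                 clip_negative = isTRUE(clip_negative),
                 replicates = as.integer(replicates)),
            class = "run_config")
}

#' Fit all models across all scenarios
#'
#' For every scenario x model pair: assemble the scenario, split 70/30,
#' fit on the training rows, and score on both the training and the
#' held-out rows.  Rows whose scenario is too small for a model, or
#' whose fit fails, are flagged (`converged = FALSE`, NA metrics), not
#' dropped.
#'
#' @param trees a `tree_records` data frame with `W_ref_kg` set (see
#'   [add_reference_agb()]).
#' @param config a [run_config].
#' @return A data frame with one row per scenario x model (x replicate),
#'   columns: `scenario`, `model`, `replicate`, `seed`, `n_train`,
#'   `n_test`, `a`, `b`, `c`, `converged`, train and test `r2`/`rmse`/
#'   `rrmse`, and `rank_test` (rank of test R^2 within scenario).
#' @export
run_model_matrix <- function(trees, config = run_config()) {
  if (any(is.na(trees$W_ref_kg)))
    stop_("W_ref_kg has missing values: call add_reference_agb() first")
  out <- list()
  for (rep_i in seq_len(config$replicates)) {
    seed <- config$seed + rep_i - 1L
    for (sc in config$scenarios) {
      ds <- assemble_scenario(trees, sc)
      sp <- split_train_test(ds, config$fraction, seed)
      for (code in config$models) {
        row <- data.frame(scenario = sc, model = code, replicate = rep_i,
                          seed = seed, n_train = nrow(sp$train),
                          n_test = nrow(sp$test),
                          a = NA_real_, b = NA_real_, c = NA_real_,
                          converged = FALSE,
                          r2_train = NA_real_, rmse_train = NA_real_,
                          rrmse_train = NA_real_,
                          r2_test = NA_real_, rmse_test = NA_real_,
                          rrmse_test = NA_real_)
        fit <- tryCatch(fit_allometric_model(code, sp$train),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          cf <- fit$coefficients
          row$a <- cf[["a"]]; row$b <- cf[["b"]]
          if (length(cf) > 2L) row$c <- cf[["c"]]
          row$converged <- fit$converged
          score <- function(d) {
            yhat <- model_predict(code, cf, d$H_m, d$R_m)
            if (config$clip_negative) yhat <- pmax(yhat, 0)
            evaluate_predictions(d$W_ref_kg, yhat)
          }
          mtr <- score(sp$train); mte <- score(sp$test)
          row$r2_train <- mtr$r2; row$rmse_train <- mtr$rmse
          row$rrmse_train <- mtr$rrmse
          row$r2_test <- mte$r2; row$rmse_test <- mte$rmse
          row$rrmse_test <- mte$rrmse
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  ## per scenario (and replicate), rank models by held-out R^2
  res$rank_test <- NA_integer_
  for (rep_i in unique(res$replicate)) for (sc in unique(res$scenario)) {
    ii <- res$replicate == rep_i & res$scenario == sc
    res$rank_test[ii] <- rank(-res$r2_test[ii], ties.method = "min",
                              na.last = "keep")
  }
  rownames(res) <- NULL
  res
}

#' Aggregate a replicated model matrix
#'
#' Mean and SD of each metric over replicates, per scenario x model.
#'
#' @param results output of [run_model_matrix()] with `replicates > 1`.
#' @export
summarize_replicates <- function(results) {
  metrics <- c("r2_train", "rmse_train", "rrmse_train",
               "r2_test", "rmse_test", "rrmse_test")
  agg <- function(f, suff) {
    a <- stats::aggregate(results[metrics],
                          by = results[c("scenario", "model")], FUN = f)
    names(a)[-(1:2)] <- paste0(metrics, suff)
    a
  }
  m <- agg(function(v) mean(v, na.rm = TRUE), "_mean")
  s <- agg(function(v) stats::sd(v, na.rm = TRUE), "_sd")
  out <- merge(m, s, by = c("scenario", "model"), sort = FALSE)
  out[order(out$scenario, match(out$model, model_codes())), ]
}

#' Write fit results to disk
#'
#' Writes `fit_results.csv`, `fit_results.json`, and a plain-text
#' per-scenario ranking summary `fit_summary.txt`.
#'
#' @param results output of [run_model_matrix()].
#' @param dir output directory (created if needed).
#' @export
write_fit_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results, file.path(dir, "fit_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results, file.path(dir, "fit_results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  lines <- character(0)
  for (sc in unique(results$scenario)) {
    sub <- results[results$scenario == sc & results$replicate == 1L, ]
    sub <- sub[order(sub$rank_test), ]
    lines <- c(lines, sprintf("Scenario %d (%s):", sc, .scenario_desc[sc]),
               sprintf("  %-4s R2(test) %7.4f  RMSE %8.2f kg  rRMSE %6.2f %%",
                       sub$model, sub$r2_test, sub$rmse_test, sub$rrmse_test),
               "")
  }
  writeLines(lines, file.path(dir, "fit_summary.txt"))
  invisible(dir)
}
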