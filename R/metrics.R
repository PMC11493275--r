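## Accuracy metrics: R^2, RMSE, rRMSE.

#' Evaluate predictions against reference values
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`,
#' `rRMSE = 100 * RMSE / ybar` (percent).
#'
#' Degenerate cases: zero variance in `y` with zero residuals gives
#' `R^2 = 0` (a constant fit explains nothing beyond the mean); zero
#' variance with nonzero residuals gives `R^2 = NA`; `ybar = 0` gives
#' `rRMSE = NA`.
#'
#' @param y reference values (kg).
#' @param yhat predicted values (kg).
#' @return list with `r2`, `rmse` (kg), `rrmse` (percent).
#' @export
evaluate_predictions <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_("y and yhat must have equal length")
  if (length(y) < 2L) stop_("need at least 2 observations")
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  eps <- 1e-12 * max(1, mean(abs(y)))^2
  r2 <- if (ss_tot <= eps) {
    if (ss_res <= eps) 0 else NA_real_
  } else 1 - ss_res / ss_tot
  rmse <- sqrt(ss_res / length(y))
  rrmse <- if (abs(mean(y)) < 1e-300) NA_real_ else 100 * rmse / mean(y)
  list(r2 = r2, rmse = rmse, rrmse = rrmse)
}
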