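test_that("reference allometry matches its printed coefficients", {
  ## frozen from high-precision evaluation of the two power laws
  expect_equal(reference_agb("larch", 20, 15), 141.4839, tolerance = 1e-4)
  expect_equal(reference_agb("ash", 12, 10), 51.65352, tolerance = 1e-4)
  ## at DBH^2 H = 1 the result is the leading coefficient exactly
  expect_identical(reference_agb("larch", 1, 1), 0.1179)
  expect_identical(reference_agb("sophora", 1, 1), 0.093)
  expect_error(reference_agb("birch", 10, 10), "unknown species")
  expect_error(reference_agb("larch", -5, 10), "> 0")
})

test_that("reference allometry is monotone and conserves DBH^2 * H", {
  expect_true(all(diff(reference_agb("larch", seq(5, 40, 5), 12)) > 0))
  expect_true(all(diff(reference_agb("ash", 15, seq(4, 25, 3))) > 0))
  ## (DBH, H) -> (k DBH, H / k^2) leaves the composite predictor fixed
  for (k in c(0.5, 1.3, 2)) {
    expect_equal(reference_agb("larch", 18 * k, 14 / k^2),
                 reference_agb("larch", 18, 14), tolerance = 1e-12)
  }
})

test_that("model forms evaluate exactly", {
  expect_equal(model_predict("Eq9", c(a = 1, b = 0, c = 0), H = 2, R = 1), 9)
  expect_equal(model_predict("Eq5", c(a = 3.7, b = 0), H = 12, R = 2), 3.7)
  expect_equal(model_predict("Eq4", c(a = 2, b = 1), H = 3, R = 0.5), 3)
  expect_equal(model_predict("Eq3", c(a = 1, b = 1), H = 2, R = 3), 11)
  expect_equal(model_predict("Eq7", c(a = 2, b = 1), H = exp(1) - 1, R = 1), 3)
  expect_error(model_predict("Eq7", c(1, 1), H = -2, R = 1), "positive")
  expect_error(model_predict("Eq1", c(1, 1), H = 0, R = 1), "positive")
  expect_equal(length(model_codes()), 9L)
  expect_equal(model_spec("Eq9")$npar, 3L)
})

test_that("exact data is recovered exactly", {
  set.seed(10)
  H <- runif(10, 5, 20); R <- runif(10, 1, 4)
  ## quadratic through its own data, >= 6 significant digits
  W9 <- 2 * (H + R)^2 + 3 * (H + R) + 1
  f9 <- fit_allometric_model("Eq9", data.frame(H_m = H, R_m = R, W_ref_kg = W9))
  expect_equal(unname(f9$coefficients), c(2, 3, 1), tolerance = 1e-7)
  ## power-of-product, parameter recovery to >= 4 s.f.
  W4 <- 0.5 * (H * R)^1.2
  f4 <- fit_allometric_model("Eq4", data.frame(H_m = H, R_m = R, W_ref_kg = W4))
  expect_equal(unname(f4$coefficients), c(0.5, 1.2), tolerance = 1e-4)
  expect_true(f4$converged)
})

test_that("every family recovers its own noise-free data to 4 s.f.", {
  set.seed(22)
  H <- runif(60, 3, 22); R <- runif(60, 0.7, 5)
  true <- list(Eq1 = c(0.2, 2.1), Eq2 = c(15, 1.8), Eq3 = c(0.8, 1.6),
               Eq4 = c(1.5, 1.3), Eq5 = c(8, 0.12), Eq6 = c(12, -30),
               Eq7 = c(150, -250), Eq8 = c(0.5, 1.9), Eq9 = c(1, 20, 50))
  for (code in model_codes()) {
    W <- model_predict(code, true[[code]], H, R)
    f <- fit_allometric_model(code, data.frame(H_m = H, R_m = R, W_ref_kg = W))
    expect_equal(unname(f$coefficients), true[[code]], tolerance = 1e-4,
                 label = code)
  }
})

test_that("flat data gives a zero slope and R^2 defined as zero", {
  d <- data.frame(H_m = c(5, 7, 9, 11), R_m = c(1, 2, 1.5, 2.5),
                  W_ref_kg = rep(42, 4))
  f <- fit_allometric_model("Eq6", d)
  expect_equal(unname(f$coefficients["a"]), 0, tolerance = 1e-10)
  expect_equal(unname(f$coefficients["b"]), 42, tolerance = 1e-10)
  m <- evaluate_predictions(d$W_ref_kg, f$fitted)
  expect_equal(m$r2, 0)
})

test_that("closed-form OLS and the iterative path agree to 1e-8", {
  set.seed(31)
  H <- runif(40, 4, 20); R <- runif(40, 1, 4)
  W <- 1.2 * (H + R)^2 - 4 * (H + R) + 60 + rnorm(40, 0, 15)
  d <- data.frame(H_m = H, R_m = R, W_ref_kg = W)
  for (code in c("Eq6", "Eq7", "Eq9")) {
    ols <- fit_allometric_model(code, d, method = "ols")
    nls <- fit_allometric_model(code, d, method = "nls")
    expect_equal(nls$coefficients, ols$coefficients, tolerance = 1e-8,
                 label = code)
  }
  expect_error(fit_allometric_model("Eq4", d, method = "ols"), "closed form")
})

test_that("a dense grid finds no lower SSE than the NLS solution", {
  set.seed(55)
  H <- runif(25, 4, 20); R <- runif(25, 1, 4)
  W <- 0.9 * (H * R)^1.15 + rnorm(25, 0, 3)
  d <- data.frame(H_m = H, R_m = R, W_ref_kg = W)
  f <- fit_allometric_model("Eq4", d)
  a0 <- f$coefficients["a"]; b0 <- f$coefficients["b"]
  sse <- function(a, b) sum((W - a * (H * R)^b)^2)
  grid <- expand.grid(a = a0 * seq(0.9, 1.1, length.out = 41),
                      b = b0 * seq(0.95, 1.05, length.out = 41))
  sses <- mapply(sse, grid$a, grid$b)
  expect_gte(min(sses), f$sse - 1e-8 * f$sse)
})

test_that("training R^2 equals squared Pearson correlation for linear fits", {
  set.seed(8)
  H <- runif(50, 4, 20); R <- runif(50, 1, 4)
  W <- 5 * (H + R) + rnorm(50, 0, 10)
  d <- data.frame(H_m = H, R_m = R, W_ref_kg = W)
  for (code in c("Eq6", "Eq7", "Eq9")) {
    f <- fit_allometric_model(code, d)
    r2 <- evaluate_predictions(W, f$fitted)$r2
    expect_equal(r2, cor(W, f$fitted)^2, tolerance = 1e-10, label = code)
  }
})

test_that("degenerate designs and tiny samples error informatively", {
  d <- data.frame(H_m = rep(5, 6), R_m = rep(2, 6), W_ref_kg = 1:6)
  expect_error(fit_allometric_model("Eq6", d), "singular")
  expect_error(fit_allometric_model("Eq9",
                                    data.frame(H_m = 1:3, R_m = 1:3,
                                               W_ref_kg = 1:3)), "at least")
})
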