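## Species allometry for reference AGB and the nine candidate
## height/crown-radius model forms.

.ref_coefs <- list(
  larch     = c(alpha = 0.1179, beta = 0.815),
  broadleaf = c(alpha = 0.0930, beta = 0.869))

.species_group <- function(species) {
  g <- ifelse(species %in% c("larch"), "larch",
              ifelse(species %in% c("ash", "sophora", "broadleaf"),
                     "broadleaf", NA_character_))
  if (anyNA(g)) stop_("unknown species: %s",
                      paste(unique(species[is.na(g)]), collapse = ", "))
  g
}

#' Reference aboveground biomass from species allometry
#'
#' `W = alpha * (DBH^2 * H)^beta` with DBH in cm, H in m, W in kg;
#' larch: alpha 0.1179, beta 0.815; ash and sophora (broadleaf group):
#' alpha 0.093, beta 0.869.
#'
#' @param species character vector (`"larch"`, `"ash"`, `"sophora"`, or
#'   the group name `"broadleaf"`).
#' @param dbh_cm diameter at breast height in cm, > 0.
#' @param h_m tree height in m, > 0.
#' @return AGB in kg.
#' @export
reference_agb <- function(species, dbh_cm, h_m) {
  if (any(dbh_cm <= 0) || any(h_m <= 0)) stop_("DBH and H must be > 0")
  g <- .species_group(species)
  cf <- do.call(rbind, .ref_coefs[g])
  cf[, "alpha"] * (dbh_cm^2 * h_m)^cf[, "beta"]
}

#' Fill the reference-AGB column of a tree table
#'
#' @param trees a `tree_records` data frame with `species`, `DBH_cm`, `H_m`.
#' @return The table with `W_ref_kg` computed via [reference_agb()].
#' @export
add_reference_agb <- function(trees) {
  trees$W_ref_kg <- reference_agb(trees$species, trees$DBH_cm, trees$H_m)
  trees
}

.model_table <- list(
  Eq1 = list(family = "power",       predictor = "H",    npar = 2L),
  Eq2 = list(family = "power",       predictor = "R",    npar = 2L),
  Eq3 = list(family = "power",       predictor = "H+R2", npar = 2L),
  Eq4 = list(family = "power",       predictor = "HR",   npar = 2L),
  Eq5 = list(family = "exponential", predictor = "H+R",  npar = 2L),
  Eq6 = list(family = "linear",      predictor = "H+R",  npar = 2L),
  Eq7 = list(family = "logarithm",   predictor = "H+R",  npar = 2L),
  Eq8 = list(family = "power",       predictor = "H+R",  npar = 2L),
  Eq9 = list(family = "quadratic",   predictor = "H+R",  npar = 3L))

#' Candidate model forms
#'
#' The nine forms combining tree height H (m) and crown radius R (m)
#' into AGB W (kg):
#' \describe{
#'   \item{Eq1}{`W = a H^b`}
#'   \item{Eq2}{`W = a R^b`}
#'   \item{Eq3}{`W = a (H + R^2)^b`}
#'   \item{Eq4}{`W = a (H R)^b`}
#'   \item{Eq5}{`W = a exp(b (H + R))`}
#'   \item{Eq6}{`W = a (H + R) + b`}
#'   \item{Eq7}{`W = a ln(H + R) + b`}
#'   \item{Eq8}{`W = a (H + R)^b`}
#'   \item{Eq9}{`W = a (H + R)^2 + b (H + R) + c`}
#' }
#'
#' @return Character vector of the nine model codes.
#' @export
model_codes <- function() names(.model_table)

#' @rdname model_codes
#' @param code one of `"Eq1"` .. `"Eq9"`.
#' @export
model_spec <- function(code) {
  code <- match.arg(code, model_codes())
  c(list(code = code), .model_table[[code]])
}

## predictor u(H, R) for each form
model_predictor <- function(code, H, R) {
  switch(.model_table[[code]]$predictor,
         "H" = H, "R" = R, "H+R2" = H + R^2, "HR" = H * R, "H+R" = H + R)
}

#' Evaluate a model form
#'
#' @param code model code `"Eq1"` .. `"Eq9"`.
#' @param coef named or positional numeric coefficients (a, b\[, c\]).
#' @param H,R tree height and crown radius in m.
#' @return Predicted AGB in kg.
#' @export
model_predict <- function(code, coef, H, R) {
  code <- match.arg(code, model_codes())
  u <- model_predictor(code, H, R)
  fam <- .model_table[[code]]$family
  a <- coef[[1]]; b <- coef[[2]]
  switch(fam,
         power = {
           if (any(u <= 0)) stop_("%s needs a strictly positive predictor", code)
           a * u^b
         },
         exponential = a * exp(b * u),
         linear = a * u + b,
         logarithm = {
           if (any(u <= 0)) stop_("%s needs a strictly positive predictor", code)
           a * log(u) + b
         },
         quadratic = a * u^2 + b * u + coef[[3]])
}

## exact linear least squares on the transformed design
ols_fit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_("singular design in linear fit")
  as.numeric(qr.coef(qrX, y))
}

## Levenberg-Marquardt for the 2-parameter nonlinear families.
## model_fn(p, u) -> (fitted, Jacobian)
lm_fit <- function(p, u, y, model_fn, tol = 1e-10, max_iter = 200L) {
  sse <- function(p) sum((y - model_fn(p, u)$f)^2)
  f0 <- sse(p)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mf <- model_fn(p, u)
    res <- y - mf$f
    J <- mf$J
    g <- crossprod(J, res)
    Hm <- crossprod(J)
    step <- tryCatch(solve(Hm + lambda * diag(ncol(J)), g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10
      if (lambda > 1e14) break
      next }
    p_new <- p + as.numeric(step)
    f1 <- sse(p_new)
    if (is.finite(f1) && f1 <= f0) {
      rel <- (f0 - f1) / max(f0, 1e-300)
      p <- p_new; f0 <- f1
      lambda <- max(lambda / 10, 1e-12)
      if (rel <= tol) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e14) { converged <- TRUE; break }  # no improving step
    }
  }
  list(par = p, sse = f0, converged = converged, iterations = it)
}

#' Fit one allometric model form
#'
#' Linear-in-parameters forms (Eq6, Eq7, Eq9) are solved by closed-form
#' least squares on the transformed design; the power forms (Eq1-4,
#' Eq8) by Levenberg-Marquardt initialized from log-log OLS; the
#' exponential form (Eq5) by Levenberg-Marquardt initialized from
#' log-linear OLS.  The objective is untransformed least squares on W.
#'
#' @param code model code `"Eq1"` .. `"Eq9"`.
#' @param data data frame with `H_m`, `R_m`, `W_ref_kg`.
#' @param method `"auto"` (closed form where exact, else NLS), `"nls"`
#'   (force the iterative path, used for oracle equivalence), or
#'   `"ols"` (closed form; only for Eq6/7/9).
#' @param tol relative-cost convergence tolerance.
#' @param max_iter iteration cap.
#' @return An `allometric_fit` list: `code`, `coefficients` (named a,
#'   b\[, c\]), `converged`, `sse`, `n`, `fitted`.
#' @export
fit_allometric_model <- function(code, data, method = c("auto", "nls", "ols"),
                                 tol = 1e-10, max_iter = 200L) {
  code <- match.arg(code, model_codes())
  method <- match.arg(method)
  spec <- .model_table[[code]]
  H <- data$H_m; R <- data$R_m; y <- data$W_ref_kg
  fin <- is.finite(H) & is.finite(R) & is.finite(y)
  H <- H[fin]; R <- R[fin]; y <- y[fin]
  n <- length(y)
  if (n < spec$npar + 1L)
    stop_("%s needs at least %d trees, got %d", code, spec$npar + 1L, n)
  u <- model_predictor(code, H, R)
  fam <- spec$family
  if (fam %in% c("power", "logarithm") && any(u <= 0))
    stop_("%s needs a strictly positive predictor over the data", code)
  converged <- TRUE
  if (fam == "linear") {
    X <- cbind(u, 1)
    cf <- if (method == "nls") lin_via_lm(X, y, tol, max_iter) else ols_fit(X, y)
  } else if (fam == "logarithm") {
    X <- cbind(log(u), 1)
    cf <- if (method == "nls") lin_via_lm(X, y, tol, max_iter) else ols_fit(X, y)
  } else if (fam == "quadratic") {
    X <- cbind(u^2, u, 1)
    cf <- if (method == "nls") lin_via_lm(X, y, tol, max_iter) else ols_fit(X, y)
  } else if (fam == "power") {
    if (method == "ols") stop_("no closed form for %s", code)
    ypos <- pmax(y, 1e-12)
    init <- ols_fit(cbind(1, log(u)), log(ypos))
    p0 <- c(exp(init[1]), init[2])
    fn <- function(p, u) list(f = p[1] * u^p[2],
                              J = cbind(u^p[2], p[1] * u^p[2] * log(u)))
    res <- lm_fit(p0, u, y, fn, tol, max_iter)
    cf <- res$par; converged <- res$converged
  } else {                                   # exponential
    if (method == "ols") stop_("no closed form for %s", code)
    ypos <- pmax(y, 1e-12)
    init <- ols_fit(cbind(1, u), log(ypos))
    p0 <- c(exp(init[1]), init[2])
    fn <- function(p, u) list(f = p[1] * exp(p[2] * u),
                              J = cbind(exp(p[2] * u),
                                        p[1] * u * exp(p[2] * u)))
    res <- lm_fit(p0, u, y, fn, tol, max_iter)
    cf <- res$par; converged <- res$converged
  }
  names(cf) <- c("a", "b", "c")[seq_along(cf)]
  fitted <- model_predict(code, cf, H, R)
  structure(list(code = code, coefficients = cf, converged = converged,
                 sse = sum((y - fitted)^2), n = n, fitted = fitted),
            class = "allometric_fit")
}

## iterative route for the linear-in-parameter forms (oracle check):
## Levenberg-Marquardt on the same design from a crude start
lin_via_lm <- function(X, y, tol, max_iter) {
  p0 <- rep(0, ncol(X))
  p0[ncol(X)] <- mean(y)
  fn <- function(p, u) list(f = as.numeric(X %*% p), J = X)
  lm_fit(p0, seq_along(y), y, fn, tol = min(tol, 1e-14),
         max_iter = max(max_iter, 500L))$par
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> %s, n = %d, SSE = %.4g, converged: %s\n",
              x$code, x$n, x$sse, x$converged))
  print(round(x$coefficients, 6))
  invisible(x)
}
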