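#' Polynomial bases for the response-surface fits
#'
#' Two built-in monomial bases in the design factors `(alpha, beta, gamma)`:
#' the reduced quadratic used for the decoloration time `R1` (no `gamma`
#' terms — inoculation day has essentially no effect on decoloration) and the
#' full 11-term quadratic-plus-three-way basis used for `R2` and `R3`.
#' Term order is fixed: intercept first, then linear, quadratic and
#' interaction terms.
#'
#' @param which `"reduced"` (`1, a, b, a2, b2, ab`) or `"full"`
#'   (`1, a, b, g, a2, b2, g2, ab, ag, bg, abg`).
#' @return a tibble with one row per term: `term` (label) and the exponents
#'   `pa`, `pb`, `pg` of `alpha`, `beta`, `gamma`.
#' @examples
#' rsm_basis("reduced")
#' @export
rsm_basis <- function(which = c("reduced", "full")) {
  which <- match.arg(which)
  full <- tibble::tribble(
    ~term,        ~pa, ~pb, ~pg,
    "(Intercept)", 0,   0,   0,
    "alpha",       1,   0,   0,
    "beta",        0,   1,   0,
    "gamma",       0,   0,   1,
    "alpha^2",     2,   0,   0,
    "beta^2",      0,   2,   0,
    "gamma^2",     0,   0,   2,
    "alpha:beta",  1,   1,   0,
    "alpha:gamma", 1,   0,   1,
    "beta:gamma",  0,   1,   1,
    "alpha:beta:gamma", 1, 1, 1
  )
  if (which == "full") return(full)
  full[full$pg == 0, ]
}

#' Design matrix of monomials
#'
#' Evaluates every basis monomial at every design point.
#'
#' @param points a data frame with columns `alpha`, `beta` and (if the basis
#'   uses it) `gamma`.
#' @param basis a basis tibble from [rsm_basis()] (or a compatible one).
#' @return a numeric matrix, one row per point, one column per term.
#' @examples
#' build_design_matrix(data.frame(alpha = 10, beta = 0.2), rsm_basis("reduced"))
#' @export
build_design_matrix <- function(points, basis = rsm_basis("full")) {
  if (is.null(dim(basis)) || nrow(basis) == 0) abort("empty basis")
  a <- points$alpha
  b <- points$beta
  g <- if (any(basis$pg > 0)) points$gamma else rep(0, length(a))
  if (any(basis$pg > 0) && is.null(points$gamma)) {
    abort("basis uses gamma but points have no gamma column")
  }
  if (!all(is.finite(c(a, b, g)))) abort("design points must be finite")
  X <- vapply(seq_len(nrow(basis)), function(j) {
    a^basis$pa[j] * b^basis$pb[j] * g^basis$pg[j]
  }, numeric(length(a)))
  X <- matrix(X, nrow = length(a))
  colnames(X) <- basis$term
  X
}

#' Ordinary least squares fit of a response surface
#'
#' Fits `y ~ X` by QR decomposition (no intercept is added: the basis itself
#' carries the constant term) and reports the coefficient of determination
#' `r^2 = 1 - SS_res / SS_tot`, with `SS_tot` about the mean. A response with
#' zero variance fits exactly; its `r^2` is defined as 1.
#'
#' @param y numeric response vector (no missing values).
#' @param X design matrix from [build_design_matrix()].
#' @param basis the basis tibble that generated `X`.
#' @param response name of the response (metadata, used in printing).
#' @param region optional named list of factor ranges (metadata for
#'   [find_optimum()] and [surface_grid()]).
#' @return an object of class `rsm_model`: coefficients, fitted values,
#'   residuals, `r.squared`, basis and region.
#' @export
fit_ols <- function(y, X, basis = NULL, response = "y", region = NULL) {
  if (anyNA(y)) abort("response contains missing values")
  if (nrow(X) <= ncol(X)) abort("need more observations than basis terms")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  coef <- qr.coef(qrX, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  structure(
    list(coefficients = coef, fitted = fitted, residuals = res,
         r.squared = r2, basis = basis, response = response,
         region = region, n = length(y)),
    class = "rsm_model"
  )
}

default_region <- function(points) {
  list(alpha = range(points$alpha), beta = range(points$beta),
       gamma = if (!is.null(points$gamma)) range(points$gamma) else c(0, 0))
}

#' Fit one response surface from a response table
#'
#' @param responses a data frame with columns `alpha`, `beta`, `gamma` and
#'   the response column.
#' @param response which response column to fit (e.g. `"R1"`, `"R2"`, `"R3"`).
#' @param basis `"reduced"`, `"full"`, or a basis tibble. The default
#'   (`"auto"`) uses the reduced (gamma-free) basis for `R1` and the full
#'   basis otherwise.
#' @return an `rsm_model`.
#' @examples
#' tab <- published_response_table()
#' fit_response_surface(tab, "R1")
#' @export
fit_response_surface <- function(responses, response = "R1", basis = "auto") {
  if (!response %in% names(responses)) {
    abort(paste0("no column ", response, " in responses"))
  }
  y <- responses[[response]]
  if (anyNA(y)) {
    bad <- which(is.na(y))
    abort(paste0("missing ", response, " in run(s): ", paste(bad, collapse = ", ")))
  }
  if (is.character(basis)) {
    basis <- switch(basis,
      auto = rsm_basis(if (response == "R1") "reduced" else "full"),
      rsm_basis(basis)
    )
  }
  X <- build_design_matrix(responses, basis)
  fit_ols(y, X, basis = basis, response = response,
          region = default_region(responses))
}

#' Fit the three response surfaces R1, R2, R3
#'
#' `R1` (full-decoloration time) is fitted on the reduced, gamma-free
#' quadratic basis; `R2` (time of peak aromatics) and `R3` (aromatics
#' depletion time) on the full 11-term basis.
#'
#' @param responses a data frame with `alpha`, `beta`, `gamma`, `R1`, `R2`,
#'   `R3` (27 factorial rows).
#' @param r1_full fit `R1` on the full basis too (for comparison); default
#'   uses the reduced basis.
#' @return a named list of three `rsm_model`s.
#' @export
fit_responses <- function(responses, r1_full = FALSE) {
  list(
    R1 = fit_response_surface(responses, "R1",
                              if (r1_full) "full" else "reduced"),
    R2 = fit_response_surface(responses, "R2", "full"),
    R3 = fit_response_surface(responses, "R3", "full")
  )
}

#' Evaluate a fitted (or published) response surface
#'
#' @param model an `rsm_model`, or a bare named coefficient vector whose
#'   names follow [rsm_basis()] term labels.
#' @param alpha,beta,gamma factor values (vectorised; `gamma` ignored by
#'   gamma-free bases).
#' @return predicted response (days).
#' @examples
#' m <- fit_response_surface(published_response_table(), "R1")
#' evaluate_model(m, alpha = 10, beta = 0.2)
#' @export
evaluate_model <- function(model, alpha, beta, gamma = 0) {
  if (inherits(model, "rsm_model")) {
    basis <- model$basis
    coef <- model$coefficients
    reg <- model$region
    if (!is.null(reg)) {
      outside <- alpha < reg$alpha[1] | alpha > reg$alpha[2] |
        beta < reg$beta[1] | beta > reg$beta[2]
      if (any(outside)) {
        warn("evaluating the response surface outside the design region")
      }
    }
  } else {
    coef <- model
    basis <- rsm_basis("full")
    basis <- basis[basis$term %in% names(coef), ]
    coef <- coef[basis$term]
  }
  n <- max(length(alpha), length(beta), length(gamma))
  pts <- tibble::tibble(alpha = rep_len(alpha, n), beta = rep_len(beta, n),
                        gamma = rep_len(gamma, n))
  drop(build_design_matrix(pts, basis) %*% coef)
}

#' @export
predict.rsm_model <- function(object, newdata, ...) {
  evaluate_model(object, newdata$alpha, newdata$beta,
                 newdata$gamma %||% 0)
}

#' Grid search for the response minimum
#'
#' Exhaustively scans a regular grid over the (box) design region and returns
#' the minimising factor combination. Ties are broken toward lower `alpha`,
#' then lower `beta`, then lower `gamma`. A quadratic on a box attains its
#' minimum either at a corner or at an interior stationary point; the default
#' 101-point-per-factor grid resolves both.
#'
#' @param model an `rsm_model` with a design region.
#' @param region optional named list of ranges overriding the model's.
#' @param n_grid grid points per factor (use 2 for corners only).
#' @return a one-row tibble: `alpha`, `beta`, `gamma`, `predicted`.
#' @export
find_optimum <- function(model, region = NULL, n_grid = 101) {
  reg <- region %||% model$region
  if (is.null(reg)) abort("no design region available")
  seq_or_const <- function(r) {
    if (diff(r) == 0) r[1] else seq(r[1], r[2], length.out = n_grid)
  }
  uses_gamma <- any(model$basis$pg > 0)
  grid <- tidyr::expand_grid(
    alpha = seq_or_const(reg$alpha),
    beta = seq_or_const(reg$beta),
    gamma = if (uses_gamma) seq_or_const(reg$gamma) else 0
  )
  pred <- evaluate_model(model, grid$alpha, grid$beta, grid$gamma)
  # alpha varies slowest and gamma fastest, so the first minimum index
  # realises the lower-alpha, then lower-beta, then lower-gamma tie-break
  i <- which.min(pred)
  tibble::tibble(alpha = grid$alpha[i], beta = grid$beta[i],
                 gamma = if (uses_gamma) grid$gamma[i] else NA_real_,
                 predicted = pred[i])
}

#' Long-format prediction grid of a response surface
#'
#' @param model an `rsm_model`.
#' @param n_grid grid points per factor.
#' @param gamma fixed inoculation day(s) at which to slice surfaces fitted
#'   with gamma terms.
#' @return a tibble `(alpha, beta, gamma, predicted)` for external plotting.
#' @export
surface_grid <- function(model, n_grid = 41, gamma = NULL) {
  reg <- model$region
  if (is.null(reg)) abort("no design region available")
  uses_gamma <- any(model$basis$pg > 0)
  gam <- if (!uses_gamma) NA_real_ else gamma %||% seq(reg$gamma[1], reg$gamma[2])
  grid <- tidyr::expand_grid(
    alpha = seq(reg$alpha[1], reg$alpha[2], length.out = n_grid),
    beta = seq(reg$beta[1], reg$beta[2], length.out = n_grid),
    gamma = gam
  )
  grid$predicted <- evaluate_model(model, grid$alpha, grid$beta,
                                   ifelse(is.na(grid$gamma), 0, grid$gamma))
  grid
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("<rsm_model> %s on %d terms, n = %d, r^2 = %.4f\n",
              x$response, length(x$coefficients), x$n, x$r.squared))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Tidy a response-surface fit
#'
#' @param x an `rsm_model`.
#' @param ... unused.
#' @return a tibble with one row per basis term: `term`, `estimate`.
#' @method tidy rsm_model
#' @export
tidy.rsm_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' One-row model summary of a response-surface fit
#'
#' @param x an `rsm_model`.
#' @param ... unused.
#' @return a tibble with `response`, `r.squared`, `df`, `nobs`.
#' @method glance rsm_model
#' @export
glance.rsm_model <- function(x, ...) {
  tibble::tibble(response = x$response, r.squared = x$r.squared,
                 df = length(x$coefficients), nobs = x$n)
}
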