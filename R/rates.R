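#' Specific growth rate of the fungus (Monod)
#'
#' Saturating Monod dependence of the fungal specific growth rate on glucose.
#'
#' @param C_glc glucose concentration, g/l (vectorised, must be >= 0).
#' @param params a [kinetic_params()] object.
#' @return specific growth rate, 1/d; in `[0, mu_max_T)`.
#' @examples
#' mu_fungus(10, kinetic_params())
#' @export
mu_fungus <- function(C_glc, params = kinetic_params()) {
  if (any(C_glc < 0)) abort("C_glc must be non-negative")
  params$mu_max_T * C_glc / (params$Ks_glc_T + C_glc)
}

#' Specific growth rate of the bacterium (Monod + Haldane-Andrews)
#'
#' Diauxic growth law: a Monod term on glucose plus a Haldane-Andrews
#' (substrate-inhibited) term on the aromatic metabolites. The aromatics term
#' is unimodal with its maximum at `C_aro = sqrt(Ks_aro * K_i)`.
#'
#' @param C_glc glucose concentration, g/l (>= 0).
#' @param C_aro aromatic metabolite concentration, g/l (>= 0).
#' @inheritParams mu_fungus
#' @return specific growth rate, 1/d.
#' @examples
#' mu_bacteria(3.68, 0, kinetic_params())  # half of mu_max_P
#' @export
mu_bacteria <- function(C_glc, C_aro, params = kinetic_params()) {
  if (any(C_glc < 0) || any(C_aro < 0)) abort("substrate concentrations must be non-negative")
  params$mu_max_P * C_glc / (params$Ks_glc_P + C_glc) +
    params$mu_max_aP * C_aro / (params$Ks_aro + C_aro + C_aro^2 / params$K_i)
}

# state: named list/vector with t, X_T, X_P, C_glc, C_enz, C_col, C_aro
state_field <- function(state, name) {
  v <- state[[name]]
  if (is.null(v)) abort(paste0("state is missing field ", name))
  v
}

#' Rate laws of the six state variables
#'
#' The right-hand sides of the coupled balance equations, one function per
#' state variable, each taking a state (a named list or one-row data frame
#' with fields `t`, `X_T`, `X_P`, `C_glc`, `C_enz`, `C_col`, `C_aro`) and the
#' kinetic parameters.
#'
#' @param state the system state; concentrations in g/l (laccase in U/l),
#'   `t` in days.
#' @param params a [kinetic_params()] object.
#' @param V_t total reaction volume, l (enters the enzyme and dye laws only).
#' @return the time derivative of the respective state variable (per day).
#' @details
#' * `deriv_fungal_biomass`: `(mu_fungus - Kd_T) * X_T`.
#' * `deriv_bacterial_biomass`: `(mu_bacteria - Kd_P) * X_P`.
#' * `deriv_glucose`: minus the sum of fungal growth demand
#'   (`mu_fungus * X_T / Y_T_glc`), laccase synthesis demand
#'   (`X_T * K_enz / Y_enz_glc`, independent of the growth rate) and
#'   bacterial demand (`X_P * mu_bacteria / Y_P_glc`); always <= 0.
#' * `deriv_enzyme`: production `K_enz * X_T * exp(mu_fungus * t)` (the
#'   exponential uses the instantaneous growth rate and absolute time; its
#'   argument is capped at 500 with a warning to avoid overflow) minus the
#'   decoloration-coupled consumption
#'   `(1/Y_col_enz) * (V_max * C_col / (K_ME_col + C_col)) * C_enz * V_t`
#'   and first-order decay `K_d * C_enz`.
#' * `deriv_dye`: Michaelis-Menten sink
#'   `-(V_max * C_col / (K_ME_col + C_col)) * C_enz * V_t`; always <= 0.
#' * `deriv_aromatics`: first-order production from the dye
#'   (`a_stoich * K_dec * C_col`) minus bacterial uptake
#'   (`mu_bacteria * X_P / Y_P_aro`). Production is deliberately first order
#'   (not the Michaelis-Menten dye sink), so dye-to-aromatics mass is not
#'   conserved by construction; this mirrors the model as published.
#' @examples
#' s <- list(t = 0, X_T = 0.025, X_P = 0, C_glc = 10, C_enz = 0,
#'           C_col = 0.2, C_aro = 0)
#' deriv_fungal_biomass(s, kinetic_params())
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
deriv_fungal_biomass <- function(state, params = kinetic_params()) {
  (mu_fungus(state_field(state, "C_glc"), params) - params$Kd_T) * state_field(state, "X_T")
}

#' @rdname rate_laws
#' @export
deriv_bacterial_biomass <- function(state, params = kinetic_params()) {
  mu <- mu_bacteria(state_field(state, "C_glc"), state_field(state, "C_aro"), params)
  (mu - params$Kd_P) * state_field(state, "X_P")
}

#' @rdname rate_laws
#' @export
deriv_glucose <- function(state, params = kinetic_params()) {
  muf <- mu_fungus(state_field(state, "C_glc"), params)
  mub <- mu_bacteria(state_field(state, "C_glc"), state_field(state, "C_aro"), params)
  X_T <- state_field(state, "X_T")
  -(muf * X_T / params$Y_T_glc +
      X_T * params$K_enz / params$Y_enz_glc +
      state_field(state, "X_P") * mub / params$Y_P_glc)
}

# cap on the exponent of the enzyme-production term; exp(500) ~ 7e216 is
# already unphysical but finite, so integration failures surface as large
# values rather than NaN
EXP_CAP <- 500

#' @rdname rate_laws
#' @export
deriv_enzyme <- function(state, params = kinetic_params(), V_t = 1.0) {
  muf <- mu_fungus(state_field(state, "C_glc"), params)
  arg <- muf * state_field(state, "t")
  if (arg > EXP_CAP) {
    warn("enzyme-production exponent capped to avoid overflow")
    arg <- EXP_CAP
  }
  mm <- params$V_max * state_field(state, "C_col") /
    (params$K_ME_col + state_field(state, "C_col"))
  params$K_enz * state_field(state, "X_T") * exp(arg) -
    ((1 / params$Y_col_enz) * mm * state_field(state, "C_enz") * V_t +
       params$K_d * state_field(state, "C_enz"))
}

#' @rdname rate_laws
#' @export
deriv_dye <- function(state, params = kinetic_params(), V_t = 1.0) {
  mm <- params$V_max * state_field(state, "C_col") /
    (params$K_ME_col + state_field(state, "C_col"))
  -mm * state_field(state, "C_enz") * V_t
}

#' @rdname rate_laws
#' @export
deriv_aromatics <- function(state, params = kinetic_params()) {
  mub <- mu_bacteria(state_field(state, "C_glc"), state_field(state, "C_aro"), params)
  params$a_stoich * params$K_dec * state_field(state, "C_col") -
    mub * state_field(state, "X_P") / params$Y_P_aro
}

#' Assembled right-hand side of the six-state system
#'
#' Evaluates all six rate laws at once, sharing the two specific-growth terms.
#' Before the inoculation day (`t < gamma`) the bacterial derivative is forced
#' to zero: no bacterium is present in the reactor yet.
#'
#' @param t absolute simulation time, d.
#' @param y numeric state vector `c(X_T, X_P, C_glc, C_enz, C_col, C_aro)`.
#' @param config a [scenario_config()] object.
#' @param params a [kinetic_params()] object.
#' @return numeric vector of six derivatives, in state order.
#' @examples
#' cfg <- scenario_config(alpha = 10, beta = 0.2, gamma = 1)
#' system_rhs(0, c(0.025, 0, 10, 0, 0.2, 0), cfg, kinetic_params())
#' @export
system_rhs <- function(t, y, config, params = kinetic_params()) {
  X_T <- y[[1]]; X_P <- y[[2]]; C_glc <- y[[3]]
  C_enz <- y[[4]]; C_col <- y[[5]]; C_aro <- y[[6]]

  muf <- params$mu_max_T * C_glc / (params$Ks_glc_T + C_glc)
  mub <- params$mu_max_P * C_glc / (params$Ks_glc_P + C_glc) +
    params$mu_max_aP * C_aro / (params$Ks_aro + C_aro + C_aro^2 / params$K_i)
  mm <- params$V_max * C_col / (params$K_ME_col + C_col)

  arg <- muf * t
  if (arg > EXP_CAP) {
    warn("enzyme-production exponent capped to avoid overflow")
    arg <- EXP_CAP
  }

  d_X_T <- (muf - params$Kd_T) * X_T
  d_X_P <- if (t < config$gamma) 0 else (mub - params$Kd_P) * X_P
  d_C_glc <- -(muf * X_T / params$Y_T_glc +
                 X_T * params$K_enz / params$Y_enz_glc +
                 X_P * mub / params$Y_P_glc)
  d_C_enz <- params$K_enz * X_T * exp(arg) -
    ((1 / params$Y_col_enz) * mm * C_enz * config$V_t + params$K_d * C_enz)
  d_C_col <- -mm * C_enz * config$V_t
  d_C_aro <- params$a_stoich * params$K_dec * C_col - mub * X_P / params$Y_P_aro

  c(d_X_T, d_X_P, d_C_glc, d_C_enz, d_C_col, d_C_aro)
}
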