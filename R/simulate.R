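#' Classical fourth-order Runge-Kutta update
#'
#' One fixed step of the classical RK4 scheme for an arbitrary right-hand
#' side. Used by the scenario integrator and directly testable on problems
#' with closed-form solutions.
#'
#' @param f function `f(t, y)` returning `dy/dt`.
#' @param t current time.
#' @param y current state (numeric vector).
#' @param dt step size (> 0).
#' @return the state advanced by `dt`.
#' @examples
#' rk4_update(function(t, y) -y, 0, 1, 0.1)  # vs exp(-0.1)
#' @export
rk4_update <- function(f, t, y, dt) {
  if (dt <= 0) abort("dt must be > 0")
  k1 <- f(t, y)
  k2 <- f(t + dt / 2, y + dt / 2 * k1)
  k3 <- f(t + dt / 2, y + dt / 2 * k2)
  k4 <- f(t + dt, y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' One RK4 step of the consortium system
#'
#' Advances the six-state system by one fixed step. Stage states are floored
#' at zero before evaluating the rate laws (all laws assume non-negative
#' concentrations), and any negative component of the result is clamped to
#' zero — glucose and dye are pure sinks that would otherwise overshoot
#' through zero on the last step before depletion.
#'
#' @param state named list with `t` and the six state fields (see
#'   [rate_laws]).
#' @param dt step size, d.
#' @param config a [scenario_config()].
#' @param params a [kinetic_params()].
#' @return the state one step later (same shape, `t` advanced by `dt`).
#' @export
rk4_step <- function(state, dt, config, params = kinetic_params()) {
  y <- as.numeric(state[STATE_VARS])
  t <- state$t
  f <- function(tt, yy) system_rhs(tt, pmax(yy, 0), config, params)
  y_new <- rk4_update(f, t, y, dt)
  if (any(!is.finite(y_new))) {
    abort(paste0("non-finite state after RK4 step at t = ", t, " in component(s): ",
                 paste(STATE_VARS[!is.finite(y_new)], collapse = ", ")))
  }
  out <- as.list(pmax(y_new, 0))
  names(out) <- STATE_VARS
  c(list(t = t + dt), out)
}

#' Integrate one scenario
#'
#' Runs the batch simulation on a uniform time grid from 0 to `t_end` with
#' step `dt`, starting from `(X_T0, 0, alpha, 0, beta, 0)`. At the grid point
#' `t = gamma` the bacterial biomass is *set* to `X_P_inoc` (a replacement,
#' modelling the discrete inoculation) before integration continues.
#'
#' @param config a [scenario_config()].
#' @param params a [kinetic_params()].
#' @return a tibble of class `dye_trajectory` with columns `t`, `X_T`, `X_P`,
#'   `C_glc`, `C_enz`, `C_col`, `C_aro`, one row per grid point; the
#'   generating `config` and `params` are attached as attributes.
#' @examples
#' traj <- simulate_scenario(scenario_config(10, 0.2, 1, t_end = 2))
#' tail(traj)
#' @export
simulate_scenario <- function(config, params = kinetic_params()) {
  stopifnot(inherits(config, "scenario_config"))
  dt <- config$dt
  n <- round(config$t_end / dt)
  ig <- round(config$gamma / dt)

  out <- matrix(NA_real_, nrow = n + 1, ncol = 7,
                dimnames = list(NULL, c("t", STATE_VARS)))
  y <- c(config$X_T0, 0, config$alpha, 0, config$beta, 0)
  if (ig == 0) y[2] <- config$X_P_inoc
  t <- 0
  out[1, ] <- c(t, y)

  for (i in seq_len(n)) {
    k1 <- system_rhs(t, y, config, params)
    k2 <- system_rhs(t + dt / 2, pmax(y + dt / 2 * k1, 0), config, params)
    k3 <- system_rhs(t + dt / 2, pmax(y + dt / 2 * k2, 0), config, params)
    k4 <- system_rhs(t + dt, pmax(y + dt * k3, 0), config, params)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    if (any(!is.finite(y))) {
      abort(paste0("non-finite state at t = ", t + dt, " in component(s): ",
                   paste(STATE_VARS[!is.finite(y)], collapse = ", ")))
    }
    t <- i * dt
    if (i == ig) y[2] <- config$X_P_inoc
    out[i + 1, ] <- c(t, y)
  }

  traj <- tibble::as_tibble(as.data.frame(out))
  attr(traj, "config") <- config
  attr(traj, "params") <- params
  class(traj) <- c("dye_trajectory", class(traj))
  traj
}

traj_config <- function(traj) {
  cfg <- attr(traj, "config")
  if (is.null(cfg)) abort("trajectory carries no scenario_config attribute")
  cfg
}

check_traj_var <- function(traj, variable) {
  if (!variable %in% names(traj)) {
    abort(paste0("unknown trajectory variable: ", variable))
  }
  variable
}

#' Peak of a trajectory variable
#'
#' @param traj a `dye_trajectory`.
#' @param variable one of the six state-variable names.
#' @return a one-row tibble with `day` and `value` of the maximum (first grid
#'   point on ties).
#' @export
peak <- function(traj, variable) {
  check_traj_var(traj, variable)
  v <- traj[[variable]]
  i <- which.max(v)  # first occurrence on ties
  tibble::tibble(day = traj$t[i], value = v[i])
}

#' Day a variable falls below (and stays below) a threshold
#'
#' Finds the first time the variable reaches `<= threshold` and remains there
#' for the rest of the trajectory, linearly interpolating between the two
#' bracketing grid points. Returns `NA` if the threshold is never attained
#' permanently within the horizon.
#'
#' @param traj a `dye_trajectory`.
#' @param variable one of the six state-variable names.
#' @param threshold absolute concentration threshold (> 0, or 0 for an
#'   identically-zero series).
#' @return the crossing day (numeric), 0 if the series starts at or below the
#'   threshold, or `NA_real_`.
#' @export
depletion_day <- function(traj, variable, threshold) {
  check_traj_var(traj, variable)
  v <- traj[[variable]]
  above <- which(v > threshold)
  if (length(above) == 0) return(0)
  i <- max(above) + 1  # first index of the permanent below-threshold tail
  if (i > length(v)) return(NA_real_)
  t0 <- traj$t[i - 1]; t1 <- traj$t[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (v0 - threshold) / (v0 - v1) * (t1 - t0)
}

#' Linear interpolation of a trajectory variable at an arbitrary day
#'
#' @inheritParams peak
#' @param day day at which to read the variable (within the grid).
#' @return interpolated value (NA if `day` is NA).
#' @export
value_at <- function(traj, variable, day) {
  check_traj_var(traj, variable)
  if (is.na(day)) return(NA_real_)
  stats::approx(traj$t, traj[[variable]], xout = day)$y
}

#' Summary statistics of one scenario
#'
#' Extracts the event times and extrema that the factorial study tabulates:
#' the fungal-biomass, laccase and bacterial-biomass peaks (day and value),
#' the complete-glucose-consumption day, and the three response variables
#' `R1` (full-decoloration day, dye below `eps_col * beta`), `R2` (day of
#' peak aromatics) and `R3` (aromatics below `eps_aro *` their peak), plus
#' the laccase activity at `R1`. All event days are interpolated between
#' grid points.
#'
#' @param traj a `dye_trajectory` as returned by [simulate_scenario()].
#' @return a one-row tibble. Events not reached within the horizon are `NA`
#'   (with a warning); a dye-free run (`beta = 0`) reports `R1 = 0` and `NA`
#'   for `R2`/`R3`.
#' @export
summarize_scenario <- function(traj) {
  cfg <- traj_config(traj)
  pk_XT <- peak(traj, "X_T")
  pk_enz <- peak(traj, "C_enz")
  pk_XP <- peak(traj, "X_P")
  pk_aro <- peak(traj, "C_aro")

  R1 <- depletion_day(traj, "C_col", cfg$eps_col * cfg$beta)
  glc_day <- depletion_day(traj, "C_glc", cfg$eps_glc * cfg$alpha)
  if (pk_aro$value > 0) {
    R2 <- pk_aro$day
    R3 <- depletion_day(traj, "C_aro", cfg$eps_aro * pk_aro$value)
  } else {
    R2 <- NA_real_
    R3 <- NA_real_
  }
  if (!is.na(R1) && is.na(R3) && pk_aro$value > 0) {
    warn(sprintf("aromatics not depleted within t_end = %g d", cfg$t_end))
  }

  tibble::tibble(
    max_X_T = pk_XT$value, day_max_X_T = pk_XT$day,
    max_enz = pk_enz$value, day_max_enz = pk_enz$day,
    glc_depletion_day = glc_day,
    max_X_P = pk_XP$value, day_max_X_P = pk_XP$day,
    R1 = R1, enz_at_R1 = value_at(traj, "C_enz", R1),
    R2 = R2, peak_aro = pk_aro$value, R3 = R3
  )
}

#' Three-level full-factorial scenario design
#'
#' Builds the 27-run design over initial glucose (`alpha`), initial dye
#' (`beta`) and inoculation day (`gamma`), in standard run order: `alpha`
#' slowest, `gamma` fastest. Levels are labelled `l`/`m`/`h` by position.
#'
#' @param alpha,beta,gamma the three factor levels each (ascending).
#' @return a 27-row tibble with `run`, the factor values, the level labels
#'   and a compact `scenario` label.
#' @examples
#' scenario_grid()
#' @export
scenario_grid <- function(alpha = c(10, 14, 20),
                          beta = c(0.2, 0.5, 1.0),
                          gamma = c(1, 2, 3)) {
  if (length(alpha) != 3 || length(beta) != 3 || length(gamma) != 3) {
    abort("scenario_grid() expects exactly three levels per factor")
  }
  lv <- c("l", "m", "h")
  grid <- tidyr::expand_grid(alpha = alpha, beta = beta, gamma = gamma)
  grid$run <- seq_len(nrow(grid))
  grid$alpha_level <- lv[match(grid$alpha, alpha)]
  grid$beta_level <- lv[match(grid$beta, beta)]
  grid$gamma_level <- lv[match(grid$gamma, gamma)]
  grid$scenario <- paste0("\u03b1", grid$alpha_level, "/\u03b2", grid$beta_level,
                          "/\u03b3", grid$gamma_level)
  dplyr::relocate(grid, "run", "scenario")
}

#' Run the full factorial of scenarios
#'
#' Simulates and summarises every run of a scenario design (by default the
#' 27-run grid of [scenario_grid()]), serially and deterministically.
#'
#' @param scenarios a data frame with columns `alpha`, `beta`, `gamma` (and
#'   optionally `run`/label columns, which are carried through).
#' @param params a [kinetic_params()].
#' @param ... further arguments passed to [scenario_config()] (e.g. `dt`,
#'   `t_end`, thresholds).
#' @return a tibble with one row per run: the design columns followed by the
#'   [summarize_scenario()] fields.
#' @examples
#' \donttest{
#' tab <- run_factorial()
#' dplyr::filter(tab, R3 == min(R3))
#' }
#' @export
run_factorial <- function(scenarios = scenario_grid(),
                          params = kinetic_params(), ...) {
  stopifnot(all(c("alpha", "beta", "gamma") %in% names(scenarios)))
  summaries <- purrr::pmap(
    list(scenarios$alpha, scenarios$beta, scenarios$gamma),
    function(a, b, g) {
      cfg <- scenario_config(alpha = a, beta = b, gamma = g, ...)
      tryCatch(
        summarize_scenario(simulate_scenario(cfg, params)),
        error = function(e) {
          abort(sprintf("scenario alpha=%g beta=%g gamma=%g failed: %s",
                        a, b, g, conditionMessage(e)))
        }
      )
    }
  )
  dplyr::bind_cols(tibble::as_tibble(scenarios), dplyr::bind_rows(summaries))
}
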