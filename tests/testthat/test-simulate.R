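params <- kinetic_params()

test_that("RK4 update reproduces the exponential to fifth-order accuracy", {
  f <- function(t, y) -y
  y1 <- rk4_update(f, 0, 1, 0.1)
  expect_equal(y1, 0.90483750, tolerance = 1e-8)
  err <- abs(y1 - exp(-0.1))
  expect_lt(err, 1e-7)
  # halving the step shrinks the one-step error ~2^5
  err_half <- abs(rk4_update(f, 0, 1, 0.05) - exp(-0.05))
  ratio <- err / err_half
  expect_gt(ratio, 2^5 * 0.85)
  expect_lt(ratio, 2^5 * 1.15)
  expect_error(rk4_update(f, 0, 1, 0), "dt")
})

test_that("a zero state is a fixed point of the stepper", {
  cfg <- scenario_config(10, 0.2, 1)
  s0 <- make_state(2, 0, 0, 0, 0, 0, 0)
  s1 <- rk4_step(s0, 0.005, cfg, params)
  expect_equal(s1$t, 2.005)
  expect_equal(unlist(s1[c("X_T", "X_P", "C_glc", "C_enz", "C_col", "C_aro")]),
               rep(0, 6), ignore_attr = TRUE)
})

test_that("scenario grid and inoculation event honour their contracts", {
  cfg <- scenario_config(10, 0.2, gamma = 1, t_end = 3)
  traj <- simulate_scenario(cfg, params)
  expect_equal(nrow(traj), 3 / 0.005 + 1)
  expect_equal(diff(traj$t), rep(0.005, nrow(traj) - 1), tolerance = 1e-12)
  # no bacterium before gamma, exactly the inoculum at gamma
  expect_true(all(traj$X_P[traj$t < 1] == 0))
  expect_equal(traj$X_P[traj$t == 1], 0.0065)
  expect_true(all(traj$X_P[traj$t > 1] > 0))
  expect_true(all(as.matrix(traj[, -1]) >= 0))
  # misaligned gamma is rejected up front
  expect_error(scenario_config(10, 0.2, gamma = 0.0033), "grid")
  expect_error(scenario_config(10, 0.2, gamma = 50), "t_end")
  # gamma = 0: inoculated from the start
  traj0 <- simulate_scenario(scenario_config(10, 0.2, gamma = 0, t_end = 0.1),
                             params)
  expect_equal(traj0$X_P[1], 0.0065)
})

test_that("a dye-free run never produces dye or metabolites", {
  cfg <- scenario_config(10, beta = 1e-9, gamma = 1, t_end = 5)
  cfg$beta <- 0  # degenerate case, bypasses the >0 constructor check
  traj <- simulate_scenario(cfg, params)
  expect_true(all(traj$C_col == 0))
  expect_true(all(traj$C_aro == 0))
  s <- summarize_scenario(traj)
  expect_equal(s$R1, 0)
  expect_true(is.na(s$R2))
  expect_true(is.na(s$R3))
})

test_that("peak, depletion and interpolation behave on hand-checkable series", {
  tr <- toy_trajectory(0:3, C_aro = c(0, 1, 3, 2))
  expect_equal(peak(tr, "C_aro"), tibble::tibble(day = 2, value = 3))
  # constant series: first grid point wins the tie
  trc <- toy_trajectory(0:3, C_enz = rep(5, 4))
  expect_equal(peak(trc, "C_enz")$day, 0)
  # monotone increasing: last grid point
  tri <- toy_trajectory(0:3, X_T = 1:4)
  expect_equal(peak(tri, "X_T")$day, 3)
  expect_error(peak(tri, "X_Q"), "unknown")

  # linear decay 1 -> 0 over [0, 1]; threshold 0.25 crossed at 0.75
  trd <- toy_trajectory(seq(0, 1, 0.25), C_col = seq(1, 0, -0.25))
  expect_equal(depletion_day(trd, "C_col", 0.25), 0.75)
  expect_equal(depletion_day(trd, "C_col", 2), 0)    # starts below
  trn <- toy_trajectory(0:3, C_col = c(4, 3, 2, 1))
  expect_true(is.na(depletion_day(trn, "C_col", 0.5)))  # never reached
  # a dip that recovers does not count: crossing is 2 + (0.6-0.2)/(0.6-0.1)
  trr <- toy_trajectory(0:4, C_col = c(1, 0.1, 0.6, 0.1, 0.05))
  expect_equal(depletion_day(trr, "C_col", 0.2), 2.8)

  expect_equal(value_at(trd, "C_col", 0.375), 0.625)
  expect_true(is.na(value_at(trd, "C_col", NA)))
})

test_that("fungal growth is essentially unaffected by the initial dye", {
  # the dye reaches the fungus only via the bacterial glucose demand (the
  # glucose balance charges the aromatics-driven part of bacterial growth),
  # so the coupling is far below biological resolution but not exactly zero
  tr_low <- reference_run(20)$traj
  cfg_hi <- scenario_config(20, 1.0, 1)
  tr_hi <- simulate_scenario(cfg_hi, params)
  expect_lt(max(abs(tr_low$X_T - tr_hi$X_T)), 1e-3)
  # before inoculation the fungal curve is bit-identical
  pre <- tr_low$t < 1
  expect_identical(tr_low$X_T[pre], tr_hi$X_T[pre])
})

test_that("trajectories match a high-accuracy adaptive reference integration", {
  skip_if_not_installed("deSolve")
  for (case in list(c(10, 0.2, 1), c(14, 0.5, 2), c(20, 1, 3))) {
    cfg <- scenario_config(case[1], case[2], case[3], t_end = 10)
    traj <- simulate_scenario(cfg, params)
    # reference formulation of the same non-negative dynamics: glucose is
    # the only state whose sink does not vanish at zero, so its rate is
    # smoothly regularised in a 1e-8 boundary layer (the fixed-step
    # integrator instead clamps states at zero each step)
    rhs_ref <- function(t, y, parms) {
      yc <- pmax(y, 0)
      d <- system_rhs(t, yc, cfg, params)
      d[3] <- d[3] * yc[3] / (yc[3] + 1e-8)
      list(d)
    }
    y0 <- c(X_T = cfg$X_T0, X_P = 0, C_glc = cfg$alpha, C_enz = 0,
            C_col = cfg$beta, C_aro = 0)
    days <- seq(1.25, 9.75, by = 0.5)  # off-grid of the inoculation day
    ref <- deSolve::lsoda(
      y0, times = sort(unique(c(0, cfg$gamma, days))), func = rhs_ref,
      events = list(data = data.frame(var = "X_P", time = cfg$gamma,
                                      value = cfg$X_P_inoc, method = "rep")),
      rtol = 1e-9, atol = 1e-12
    )
    ref <- as.data.frame(ref)
    rows <- match(days, ref$time)
    for (v in c("X_T", "X_P", "C_glc", "C_enz", "C_col", "C_aro")) {
      ours <- sapply(days, function(d) value_at(traj, v, d))
      scale <- max(abs(ref[[v]]), 1e-12)
      expect_lt(max(abs(ours - ref[[v]][rows]) / scale), 0.005,
                label = paste("rel error in", v))
    }
  }
})

test_that("event times are converged at the default step size", {
  s_default <- reference_run(20)$summary
  cfg_half <- scenario_config(20, 0.2, 1, dt = 0.0025)
  s_half <- summarize_scenario(simulate_scenario(cfg_half, params))
  expect_lt(abs(s_default$R1 - s_half$R1), 0.02)
  expect_lt(abs(s_default$R2 - s_half$R2), 0.02)
  expect_lt(abs(s_default$R3 - s_half$R3), 0.02)
})

test_that("the full factorial runs deterministically in design order", {
  tab <- default_factorial()
  expect_equal(nrow(tab), 27)
  expect_equal(tab$run, 1:27)
  # design order: alpha slowest, gamma fastest
  expect_equal(tab$alpha, rep(c(10, 14, 20), each = 9))
  expect_equal(tab$gamma, rep(1:3, 9))
  expect_false(anyNA(tab[, c("R1", "R2", "R3")]))
  # decoloration is indifferent to inoculation day (within one step)
  by_ab <- split(tab$R1, paste(tab$alpha, tab$beta))
  for (g in by_ab) expect_lt(diff(range(g)), 0.005 + 1e-9)
  # re-running two scenarios reproduces identical summaries
  redo <- run_factorial(scenario_grid()[c(1, 19), ], params)
  expect_identical(redo$R1, tab$R1[c(1, 19)])
  expect_identical(redo$R3, tab$R3[c(1, 19)])
})

test_that("states stay non-negative and sinks are monotone across all runs", {
  for (r in default_runs()) {
    m <- as.matrix(r$traj[, -1])
    expect_true(all(m >= 0))
    expect_true(all(diff(r$traj$C_glc) <= 1e-12))
    expect_true(all(diff(r$traj$C_col) <= 1e-12))
  }
})
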