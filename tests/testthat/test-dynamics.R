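test_that("linear driver derivative evaluates the weighted driver sum", {
  p <- linear_driver_params(1, 1, 1, 1)
  drv <- driver_signals(S = 1, P = 1, E_env = 1, C_exo = 3)
  expect_equal(health_derivative_linear(0, 0, drv, p), 0)

  drv0 <- driver_signals(S = 0, P = 0, E_env = 0, C_exo = 0)
  expect_equal(health_derivative_linear(5, 2, drv0, p), 0)

  p2 <- linear_driver_params(0.5, 0.3, 0.2, 0.1)
  drv2 <- driver_signals(S = 2, P = 1, E_env = 1, C_exo = 5)
  expect_equal(health_derivative_linear(0, 0, drv2, p2), 1.0)

  # derivative is independent of H, by design
  expect_equal(health_derivative_linear(-10, 0, drv2, p2),
               health_derivative_linear(10, 0, drv2, p2))

  drv_noC <- driver_signals(S = 1, P = 1, E_env = 1)
  expect_error(health_derivative_linear(0, 0, drv_noC, p), "C_exo")
})

test_that("linear derivative is linear in the parameter vector", {
  drv <- driver_signals(S = function(t) sin(t) + 2, P = 0.7,
                        E_env = function(t) cos(t), C_exo = 1.3)
  set.seed(11)
  for (rep in 1:20) {
    th <- runif(4, 0.1, 2)
    p1 <- linear_driver_params(th[1], th[2], th[3], th[4])
    p2 <- linear_driver_params(2 * th[1], 2 * th[2], 2 * th[3], 2 * th[4])
    tt <- runif(5, 0, 10)
    expect_equal(health_derivative_linear(0, tt, drv, p2),
                 2 * health_derivative_linear(0, tt, drv, p1))
  }
})

test_that("environment-suppressed derivative and its limits", {
  drv <- driver_signals(E_env = 1, C_exo = 2)
  p <- env_resource_params(alpha_r = 1, kappa = 1, beta = 0.5)
  expect_equal(health_derivative_env(0, 0, R_h = 2, drv, p), 0)

  # kappa = 0 removes the environmental inhibition entirely
  p0 <- env_resource_params(1, 0, 0.5)
  for (E in c(0, 5, 100)) {
    drvE <- driver_signals(E_env = E, C_exo = 2)
    expect_equal(health_derivative_env(0, 0, 2, drvE, p0), 1 * 2 - 0.5 * 2)
  }

  # monotone non-increasing in E; limit -> -beta*C from above
  Es <- c(0, 1, 10, 100, 1e4, 1e6)
  d <- vapply(Es, function(E) {
    health_derivative_env(0, 0, 2, driver_signals(E_env = E, C_exo = 2), p)
  }, numeric(1))
  expect_true(all(diff(d) <= 0))
  expect_true(all(d > -0.5 * 2))
  expect_equal(d[length(d)], -1, tolerance = 1e-5)

  # inadmissible denominator reports t and E
  pneg <- env_resource_params(1, 2, 0.5)
  drv_bad <- driver_signals(E_env = -1, C_exo = 0)
  expect_error(health_derivative_env(0, 3, 1, drv_bad, pneg), "t = 3")
})

test_that("simulate_trajectory matches the closed form for constant drivers", {
  # net drive g = 1: alpha.(1,1,1).(1,1,1) - 1*2 = 1
  spec <- linear_model_spec(
    linear_driver_params(1, 1, 1, 1),
    driver_signals(S = 1, P = 1, E_env = 1, C_exo = 2))
  tg <- seq(0, 10, by = 0.1)
  traj <- simulate_trajectory(0, spec, tg)
  expect_s3_class(traj, "health_state")
  expect_identical(traj$H[1], 0)
  expect_lt(max(abs(traj$H - tg)), 1e-6)

  # zero drivers: constant trajectory
  spec0 <- linear_model_spec(
    linear_driver_params(1, 1, 1, 1),
    driver_signals(S = 0, P = 0, E_env = 0, C_exo = 0))
  traj0 <- simulate_trajectory(1.5, spec0, seq(0, 5, by = 0.5))
  expect_equal(traj0$H, rep(1.5, 11))
})

test_that("closed-loop RK4 matches the adaptive reference integrator", {
  spec <- closed_loop_spec(
    env_resource_params(alpha_r = 1, kappa = 0.5, beta = 0.5),
    logistic_allocation_params(10, -1),
    social_cost_params(C0 = 1, delta_sc = 0.2, eta = 0.5),
    driver_signals(S = 1, P = 0.5,
                   E_env = function(t) 0.5 + 0.3 * sin(t), R_exo = 1))
  tg <- seq(0, 10, by = 0.05)
  rk4 <- simulate_trajectory(0.5, spec, tg, method = "rk4")
  ref <- simulate_trajectory(0.5, spec, tg, method = "adaptive", tol = 1e-12)
  expect_lt(max(abs(rk4$H - ref$H)), 1e-5)
})

test_that("find_equilibrium solves the closed-loop balance", {
  # alpha*lam*sigma(gamma H)/(1+kappa E) = beta*C with q = 0.5 -> H* = 0
  spec <- closed_loop_spec(
    env_resource_params(1, 0, 1),
    logistic_allocation_params(2, 1),
    social_cost_params(C0 = 1, delta_sc = 0, eta = 0),
    driver_signals(S = 0, E_env = 0))
  Hstar <- find_equilibrium(spec)
  expect_equal(Hstar, 0)

  # general case: plugging H* back gives |dH/dt| < 1e-10
  spec2 <- closed_loop_spec(
    env_resource_params(1.3, 0.4, 0.7),
    logistic_allocation_params(5, -1.2),
    social_cost_params(C0 = 2, delta_sc = 0.3, eta = 0.5),
    driver_signals(S = 1, E_env = 0.8, R_exo = 1))
  Hstar2 <- find_equilibrium(spec2)
  expect_true(is.finite(Hstar2))
  f <- eldersim:::model_rhs(spec2)
  expect_lt(abs(f(0, Hstar2)), 1e-10)

  # cost too high for the sigmoid to balance -> no equilibrium
  spec_none <- closed_loop_spec(
    env_resource_params(1, 0, 1),
    logistic_allocation_params(2, 1),
    social_cost_params(C0 = 3, delta_sc = 0, eta = 0),
    driver_signals(S = 0, E_env = 0))
  expect_true(is.na(find_equilibrium(spec_none)))

  spec_g0 <- spec2
  spec_g0$allocation$gamma_sens <- 0
  expect_error(find_equilibrium(spec_g0), "gamma")
})

test_that("equilibria are attracting under negative feedback (gamma < 0)", {
  spec <- closed_loop_spec(
    env_resource_params(1, 0, 1),
    logistic_allocation_params(2, -1),
    social_cost_params(C0 = 1, delta_sc = 0, eta = 0),
    driver_signals(S = 0, E_env = 0))
  Hstar <- find_equilibrium(spec)
  expect_equal(Hstar, 0)
  tg <- seq(0, 40, by = 0.1)
  for (H0 in Hstar + c(-0.5, 0.5)) {
    traj <- simulate_trajectory(H0, spec, tg)
    expect_lt(abs(traj$H[length(tg)] - Hstar), 1e-3)
  }
})

test_that("calibrate_linear recovers generating parameters (noiseless)", {
  drv <- calib_drivers()
  truth <- linear_driver_params(0.5, 0.3, 0.2, 0.1)
  tg <- seq(0, 10, length.out = 200)
  traj <- simulate_trajectory(0, linear_model_spec(truth, drv), tg)
  fit <- calibrate_linear(traj, drv)
  est <- unlist(fit$params)
  expect_lt(max(abs(est - unlist(truth)) / unlist(truth)), 1e-2)
  expect_identical(fit$diagnostics$rank, 4L)
  expect_true(is.finite(fit$diagnostics$condition))
})

test_that("calibrate_linear rejects rank-deficient regressors", {
  drv <- driver_signals(S = 1, P = 2, E_env = 0.5, C_exo = 1)
  traj <- health_state(seq(0, 10, by = 0.1), seq(0, 10, by = 0.1) * 0.3)
  expect_error(calibrate_linear(traj, drv), "identifiab")
})

test_that("calibrate_linear tolerates observation noise (10% at sd 0.01)", {
  drv <- calib_drivers(amp = 2)
  truth <- linear_driver_params(0.5, 0.3, 0.2, 0.2)
  tg <- seq(0, 10, length.out = 500)
  traj <- simulate_trajectory(0, linear_model_spec(truth, drv), tg)
  set.seed(2024)
  noisy <- health_state(tg, traj$H + rnorm(500, 0, 0.01))
  fit <- calibrate_linear(noisy, drv)
  est <- unlist(fit$params)
  expect_lt(max(abs(est - unlist(truth)) / unlist(truth)), 0.10)
})

test_that("health_state validates its invariants", {
  expect_error(health_state(c(0, 1, 1), c(0, 0, 0)), "strictly increasing")
  expect_error(health_state(c(0, 1), c(0, NaN)), "finite")
})
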