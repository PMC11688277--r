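# Health-state dynamics: the two dH/dt variants, trajectory simulation,
# equilibrium analysis and least-squares parameter recovery.

#' Health-state trajectory container
#'
#' A trajectory of the scalar health index \eqn{H} on a strictly increasing
#' time grid.  \eqn{H} is a dimensionless standardised index; it is unbounded
#' by construction (the linear driver model has no mean reversion and can
#' drift) and a working range of about \[-3, 3\] is recommended.
#'
#' @param t strictly increasing numeric time grid (default unit: days).
#' @param H finite health-index values, one per grid point.
#' @return object of class `health_state` (a data.frame with columns `t`, `H`).
#' @export
health_state <- function(t, H) {
  if (length(t) != length(H))
    stop("t and H must have equal length", call. = FALSE)
  if (length(t) < 1L) stop("empty trajectory", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (!all(is.finite(H)))
    stop("H must be finite at every grid point; first bad t = ",
         t[which(!is.finite(H))[1]], call. = FALSE)
  structure(data.frame(t = as.numeric(t), H = as.numeric(H)),
            class = c("health_state", "data.frame"))
}

#' Linear driver-model derivative
#'
#' Right-hand side of the open-loop health model,
#' \eqn{dH/dt = \alpha_1 S(t) + \alpha_2 P(t) + \alpha_3 E(t) - \beta C(t)}.
#' The derivative is deliberately independent of `H`: the model as stated
#' has no health feedback, and that property is preserved literally.
#'
#' @param H health index (ignored by the model; kept for the common
#'   derivative signature).
#' @param t time (may be a vector).
#' @param drivers a [driver_signals()] object; `C_exo` must be present.
#' @param params a [linear_driver_params()] object.
#' @return the derivative \eqn{dH/dt} at `t`.
#' @examples
#' drv <- driver_signals(S = 2, P = 1, E_env = 1, C_exo = 5)
#' p <- linear_driver_params(0.5, 0.3, 0.2, 0.1)
#' health_derivative_linear(0, 0, drv, p)  # 1.0
#' @export
health_derivative_linear <- function(H, t, drivers, params) {
  stopifnot(inherits(params, "linear_driver_params"), is_driver_signals(drivers))
  if (is.null(drivers$C_exo))
    stop("linear driver model requires the exogenous cost signal 'C_exo'",
         call. = FALSE)
  params$alpha1 * drivers$S(t) + params$alpha2 * drivers$P(t) +
    params$alpha3 * drivers$E_env(t) - params$beta * drivers$C_exo(t)
}

#' Environment-suppressed resource-model derivative
#'
#' Right-hand side of \eqn{dH/dt = \alpha R_h/(1+\kappa E(t)) - \beta C(t)}:
#' the health return on resources \eqn{R_h} is divided by \eqn{1+\kappa E},
#' so a deteriorating environment inhibits improvement.
#'
#' @param H health index (unused; common signature).
#' @param t time.
#' @param R_h resources received at `t`.
#' @param drivers a [driver_signals()] object supplying `E_env` and the cost
#'   channel `C_exo` (in closed-loop use, `C_exo` is the social-capital cost
#'   computed from the cost model).
#' @param params an [env_resource_params()] object.
#' @return the derivative \eqn{dH/dt} at `t`.
#' @export
health_derivative_env <- function(H, t, R_h, drivers, params) {
  stopifnot(inherits(params, "env_resource_params"), is_driver_signals(drivers))
  if (is.null(drivers$C_exo))
    stop("environment-resource model requires the cost signal 'C_exo'",
         call. = FALSE)
  C <- drivers$C_exo(t)
  E <- drivers$E_env(t)
  denom <- 1 + params$kappa * E
  if (any(denom <= 0)) {
    i <- which(denom <= 0)[1]
    stop("inadmissible environment: 1 + kappa*E <= 0 at t = ", t[i],
         " (E = ", E[i], ")", call. = FALSE)
  }
  params$alpha_r * R_h / denom - params$beta * C
}

# Build the scalar RHS f(t, H) for a model spec.
model_rhs <- function(spec) {
  if (inherits(spec, "linear_model_spec")) {
    function(t, H) health_derivative_linear(H, t, spec$drivers, spec$params)
  } else if (inherits(spec, "closed_loop_spec")) {
    drv <- spec$drivers
    Rm <- if (is.null(drv$R_exo)) function(t) rep(0, length(t)) else drv$R_exo
    # cost enters the dynamics through the C_exo channel, recomputed from the
    # social-capital model at every evaluation
    drv_cl <- drv
    drv_cl$C_exo <- function(t)
      behavior_cost(Sc = drv$S(t), Rm = Rm(t), params = spec$cost)
    function(t, H) {
      R_h <- logistic_allocation(H, spec$allocation)
      health_derivative_env(H, t, R_h, drv_cl, spec$env_resource)
    }
  } else {
    stop("spec must be a linear_model_spec or closed_loop_spec", call. = FALSE)
  }
}

#' Simulate a health-state trajectory
#'
#' Integrates one of the two model variants over a strictly increasing time
#' grid.  The closed-loop variant recomputes the logistic allocation and the
#' social-capital cost at every integrator evaluation.
#'
#' @param H0 initial health index.
#' @param spec a [linear_model_spec()] or [closed_loop_spec()].
#' @param t_grid strictly increasing time grid; the first value is the
#'   initial time and the fixed-step integrator takes one step per interval.
#' @param method `"rk4"` (default, fixed step from the grid) or `"adaptive"`
#'   (step-doubling RK4 with local error control, the reference integrator).
#' @param tol local error tolerance for the adaptive method.
#' @return a [health_state()] trajectory with `H[1] == H0`.
#' @examples
#' spec <- linear_model_spec(linear_driver_params(1, 1, 1, 1),
#'                           driver_signals(S = 1, P = 1, E_env = 1, C_exo = 2))
#' traj <- simulate_trajectory(0, spec, seq(0, 5, by = 0.1))
#' tail(traj, 1)  # H(5) = 5 for net drive 1
#' @export
simulate_trajectory <- function(H0, spec, t_grid,
                                method = c("rk4", "adaptive"), tol = 1e-10) {
  method <- match.arg(method)
  H0 <- chk_num1(H0, "H0")
  if (length(t_grid) < 2L || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing with >= 2 points", call. = FALSE)
  f <- model_rhs(spec)
  H <- switch(method,
    rk4      = integrate_rk4(f, H0, t_grid),
    adaptive = integrate_adaptive(f, H0, t_grid, tol = tol))
  health_state(t_grid, H)
}

#' Closed-loop equilibrium of the environment-suppressed model
#'
#' With constant drivers, the coupled system
#' \eqn{dH/dt = \alpha \lambda \sigma(\gamma H)/(1+\kappa E) - \beta C}
#' has the root
#' \eqn{H^* = \mathrm{logit}(q)/\gamma} with
#' \eqn{q = \beta C (1+\kappa E) / (\alpha \lambda)}.  When \eqn{q} falls
#' outside \eqn{(0, 1)} the sigmoid cannot balance the cost and no
#' equilibrium exists.
#'
#' @param spec a [closed_loop_spec()] whose drivers are constant (evaluated
#'   at `t_eval`).
#' @param t_eval time at which the constant drivers are read (default 0).
#' @return the equilibrium health index `H*`, or `NA_real_` when none exists.
#' @export
find_equilibrium <- function(spec, t_eval = 0) {
  stopifnot(inherits(spec, "closed_loop_spec"))
  gam <- spec$allocation$gamma_sens
  if (gam == 0)
    stop("gamma_sens = 0: allocation is insensitive to health, no unique root",
         call. = FALSE)
  drv <- spec$drivers
  E <- drv$E_env(t_eval)
  Rm <- if (is.null(drv$R_exo)) 0 else drv$R_exo(t_eval)
  C <- behavior_cost(Sc = drv$S(t_eval), Rm = Rm, params = spec$cost)
  q <- spec$env_resource$beta * C * (1 + spec$env_resource$kappa * E) /
    (spec$env_resource$alpha_r * spec$allocation$lam_total)
  if (!is.finite(q) || q <= 0 || q >= 1) return(NA_real_)
  log(q / (1 - q)) / gam
}

#' Recover linear driver-model parameters from an observed trajectory
#'
#' Estimates \eqn{(\alpha_1,\alpha_2,\alpha_3,\beta)} by ordinary least
#' squares of finite-difference derivatives (central on interior points,
#' one-sided at the ends) on the regressor matrix
#' \eqn{[S, P, E, -C]} evaluated on the trajectory grid.  Derivative noise
#' handling is the caller's concern; an optional moving-average smoother on
#' `H` is available but off by default.
#'
#' @param trajectory a [health_state()] trajectory (>= 5 points).
#' @param drivers a [driver_signals()] object with `C_exo` present.
#' @param smooth_window odd integer window for an optional pre-fit moving
#'   average on `H`; `1` (default) disables smoothing.
#' @return a list with `params` (a [linear_driver_params()]), and
#'   `diagnostics`: regressor `rank`, `condition` number, residual `rms`
#'   and the number of points used.
#' @export
calibrate_linear <- function(trajectory, drivers, smooth_window = 1L) {
  stopifnot(inherits(trajectory, "health_state"), is_driver_signals(drivers))
  if (is.null(drivers$C_exo))
    stop("calibration requires the exogenous cost signal 'C_exo'", call. = FALSE)
  t <- trajectory$t
  H <- trajectory$H
  n <- length(t)
  if (n < 5L) stop("need at least 5 grid points to calibrate", call. = FALSE)
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    if (k %% 2L == 0L) stop("smooth_window must be odd", call. = FALSE)
    H <- stats::filter(H, rep(1 / k, k), sides = 2)
    keep <- !is.na(H)
    H <- as.numeric(H[keep]); t <- t[keep]; n <- length(t)
  }
  # finite-difference dH/dt: central interior, one-sided ends
  dH <- numeric(n)
  dH[1] <- (H[2] - H[1]) / (t[2] - t[1])
  dH[n] <- (H[n] - H[n - 1]) / (t[n] - t[n - 1])
  mid <- 2:(n - 1)
  dH[mid] <- (H[mid + 1] - H[mid - 1]) / (t[mid + 1] - t[mid - 1])

  X <- cbind(S = drivers$S(t), P = drivers$P(t), E = drivers$E_env(t),
             negC = -drivers$C_exo(t))
  sv <- svd(X)$d
  rank <- sum(sv > max(dim(X)) * .Machine$double.eps * sv[1])
  cond <- if (rank == ncol(X)) sv[1] / sv[length(sv)] else Inf
  if (rank < ncol(X))
    stop("regressors are rank-deficient (rank ", rank,
         " of 4): parameters are not identifiable from these drivers",
         call. = FALSE)
  fit <- qr.solve(X, dH)
  resid <- dH - X %*% fit
  list(
    params = linear_driver_params(fit[1], fit[2], fit[3], fit[4]),
    diagnostics = list(rank = rank, condition = cond,
                       rms = sqrt(mean(resid^2)), n = n)
  )
}
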