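# Parameter bundles for the dynamics, allocation and economics layers.
# Constructors validate eagerly so downstream code can assume admissibility.

chk_num1 <- function(x, nm, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", nm, "' must be a single non-NA number", call. = FALSE)
  if (finite && !is.finite(x))
    stop("'", nm, "' must be finite", call. = FALSE)
  as.numeric(x)
}

#' Linear driver-model parameters
#'
#' Gains of the open-loop health model
#' \eqn{dH/dt = \alpha_1 S + \alpha_2 P + \alpha_3 E - \beta C}.
#'
#' @param alpha1,alpha2,alpha3 driver gains (per unit time).
#' @param beta cost gain (per unit time).
#' @return object of class `linear_driver_params`.
#' @export
linear_driver_params <- function(alpha1, alpha2, alpha3, beta) {
  obj <- list(
    alpha1 = chk_num1(alpha1, "alpha1"),
    alpha2 = chk_num1(alpha2, "alpha2"),
    alpha3 = chk_num1(alpha3, "alpha3"),
    beta   = chk_num1(beta, "beta")
  )
  structure(obj, class = "linear_driver_params")
}

#' Environment-suppressed resource-model parameters
#'
#' Parameters of \eqn{dH/dt = \alpha R_h/(1+\kappa E) - \beta C}: the
#' resource gain `alpha_r`, the environmental inhibition coefficient `kappa`
#' (worse environments suppress the health return on resources), and the
#' cost gain `beta`.
#'
#' @param alpha_r resource gain.
#' @param kappa environmental inhibition coefficient, `>= 0`.
#' @param beta cost gain.
#' @return object of class `env_resource_params`.
#' @export
env_resource_params <- function(alpha_r, kappa, beta) {
  kappa <- chk_num1(kappa, "kappa")
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  structure(list(
    alpha_r = chk_num1(alpha_r, "alpha_r"),
    kappa   = kappa,
    beta    = chk_num1(beta, "beta")
  ), class = "env_resource_params")
}

#' Saturating utility-function parameters
#'
#' Parameters of \eqn{U(R) = a R^{\theta} / (1 + b R^{\delta})}.  `delta_u`
#' is the denominator exponent (named to avoid the social-capital impact
#' factor `delta_sc` of the cost model).
#'
#' @param a utility coefficient, `> 0`.
#' @param b saturation coefficient, `>= 0`.
#' @param theta numerator exponent, `> 0`.
#' @param delta_u denominator exponent, `> 0`.
#' @return object of class `utility_params`.
#' @export
utility_params <- function(a, b, theta, delta_u) {
  a <- chk_num1(a, "a"); b <- chk_num1(b, "b")
  theta <- chk_num1(theta, "theta"); delta_u <- chk_num1(delta_u, "delta_u")
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (b < 0) stop("'b' must be >= 0", call. = FALSE)
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  if (delta_u <= 0) stop("'delta_u' must be > 0", call. = FALSE)
  structure(list(a = a, b = b, theta = theta, delta_u = delta_u),
            class = "utility_params")
}

#' Logistic allocation-rule parameters
#'
#' Parameters of the health-sensitive feedback rule
#' \eqn{R_h = \lambda \, e^{\gamma H}/(1+e^{\gamma H})}.  With `gamma_sens`
#' positive the rule as written gives more resources at *higher* health;
#' the narrative behaviour (support the frail) corresponds to
#' `gamma_sens < 0`, which is what the shipped scenario configurations use.
#'
#' @param lam_total total resource amount \eqn{\lambda > 0}.
#' @param gamma_sens health sensitivity coefficient (nonzero; `gamma_sens = 0`
#'   degenerates to a constant \eqn{\lambda/2} and is flagged with a warning).
#' @return object of class `logistic_allocation_params`.
#' @export
logistic_allocation_params <- function(lam_total, gamma_sens) {
  lam_total <- chk_num1(lam_total, "lam_total")
  gamma_sens <- chk_num1(gamma_sens, "gamma_sens")
  if (lam_total <= 0) stop("'lam_total' must be > 0", call. = FALSE)
  if (gamma_sens == 0)
    warning("gamma_sens = 0: allocation is constant at lam_total/2",
            call. = FALSE)
  structure(list(lam_total = lam_total, gamma_sens = gamma_sens),
            class = "logistic_allocation_params")
}

#' Social-capital cost-model parameters
#'
#' Parameters of \eqn{C = C_0 (1 - \delta S_c / (1 + \eta R_m))}: baseline
#' behaviour cost `C0`, social-capital impact factor `delta_sc` and resource
#' sensitivity `eta`.  Admissibility (\eqn{\delta S_c/(1+\eta R_m) \le 1}) is
#' checked at evaluation time by [behavior_cost()].
#'
#' @param C0 baseline behaviour cost, `>= 0`.
#' @param delta_sc social-capital impact factor, `>= 0`.
#' @param eta resource sensitivity coefficient, `>= 0`.
#' @return object of class `social_cost_params`.
#' @export
social_cost_params <- function(C0, delta_sc, eta) {
  C0 <- chk_num1(C0, "C0"); delta_sc <- chk_num1(delta_sc, "delta_sc")
  eta <- chk_num1(eta, "eta")
  if (C0 < 0) stop("'C0' must be >= 0", call. = FALSE)
  if (delta_sc < 0) stop("'delta_sc' must be >= 0", call. = FALSE)
  if (eta < 0) stop("'eta' must be >= 0", call. = FALSE)
  structure(list(C0 = C0, delta_sc = delta_sc, eta = eta),
            class = "social_cost_params")
}

#' Closed-loop model specification
#'
#' Couples the environment-suppressed dynamics with the logistic allocation
#' feedback and the social-capital cost model: at every integrator
#' evaluation, resources are recomputed as
#' \eqn{R_h(t) = \lambda\sigma(\gamma H(t))} and the behaviour cost as
#' \eqn{C(t) = C_0(1-\delta S_c(t)/(1+\eta R_m(t)))}, where by package
#' convention the social-capital support \eqn{S_c(t)} is the `S` driver
#' channel and the social-capital resource input \eqn{R_m(t)} is the `R_exo`
#' channel (zero when absent).
#'
#' @param env_resource an [env_resource_params()] object.
#' @param allocation a [logistic_allocation_params()] object.
#' @param cost a [social_cost_params()] object.
#' @param drivers a [driver_signals()] object.
#' @return object of class `closed_loop_spec`.
#' @export
closed_loop_spec <- function(env_resource, allocation, cost, drivers) {
  stopifnot(inherits(env_resource, "env_resource_params"),
            inherits(allocation, "logistic_allocation_params"),
            inherits(cost, "social_cost_params"),
            is_driver_signals(drivers))
  structure(list(env_resource = env_resource, allocation = allocation,
                 cost = cost, drivers = drivers),
            class = "closed_loop_spec")
}

#' Open-loop linear-driver model specification
#'
#' @param params a [linear_driver_params()] object.
#' @param drivers a [driver_signals()] object; the `C_exo` channel is
#'   mandatory (the linear model takes its cost signal exogenously).
#' @return object of class `linear_model_spec`.
#' @export
linear_model_spec <- function(params, drivers) {
  stopifnot(inherits(params, "linear_driver_params"),
            is_driver_signals(drivers))
  if (is.null(drivers$C_exo))
    stop("linear driver model requires the exogenous cost signal 'C_exo'",
         call. = FALSE)
  structure(list(params = params, drivers = drivers),
            class = "linear_model_spec")
}
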