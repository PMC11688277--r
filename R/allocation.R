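# Resource allocation: saturating utility, concavity check, health-sensitive
# logistic feedback rule, and budget-constrained utility maximisation via
# bisection on the shared Lagrange multiplier.

#' Saturating utility of allocated resources
#'
#' Evaluates \eqn{U(R) = a R^{\theta} / (1 + b R^{\delta})}, the
#' diminishing-marginal-returns utility of giving `R` resources to one
#' individual. `U(0) = 0` for all valid parameter sets.
#'
#' @param R resources, `>= 0` (vectorised).
#' @param params a [utility_params()] object.
#' @return utility value(s).
#' @examples
#' utility(3, utility_params(a = 2, b = 1, theta = 2, delta_u = 1))  # 4.5
#' @export
utility <- function(R, params) {
  stopifnot(inherits(params, "utility_params"))
  if (any(R < 0)) stop("R must be >= 0", call. = FALSE)
  params$a * R^params$theta / (1 + params$b * R^params$delta_u)
}

# Analytic marginal utility U'(R) = a R^(theta-1) *
#   [theta + b R^delta (theta - delta)] / (1 + b R^delta)^2
marginal_utility <- function(R, params) {
  a <- params$a; b <- params$b; th <- params$theta; de <- params$delta_u
  Rd <- R^de
  a * R^(th - 1) * (th + b * Rd * (th - de)) / (1 + b * Rd)^2
}

#' Check diminishing marginal returns numerically
#'
#' Verifies on a grid over `(0, R_max]` that the central-difference marginal
#' utility is non-increasing, i.e. that the utility exhibits diminishing
#' marginal returns over the range of interest.
#'
#' @param params a [utility_params()] object.
#' @param R_max upper end of the resource range to check, `> 0`.
#' @param n_grid number of grid points, `>= 3`.
#' @param tol relative tolerance on marginal-utility increases.
#' @return a list with `ok` (logical) and `first_violation` (the smallest `R`
#'   at which marginal utility increases, or `NA` when `ok`).
#' @export
check_diminishing_returns <- function(params, R_max, n_grid = 201L,
                                      tol = 1e-9) {
  stopifnot(inherits(params, "utility_params"))
  if (R_max <= 0) stop("R_max must be > 0", call. = FALSE)
  if (n_grid < 3L) stop("n_grid must be >= 3", call. = FALSE)
  R <- seq(R_max / n_grid, R_max, length.out = n_grid)
  h <- R[2] - R[1]
  mu <- (utility(R + h / 2, params) - utility(pmax(R - h / 2, 0), params)) / h
  dmu <- diff(mu)
  viol <- which(dmu > tol * pmax(abs(mu[-length(mu)]), 1))
  if (length(viol) == 0L) list(ok = TRUE, first_violation = NA_real_)
  else list(ok = FALSE, first_violation = R[viol[1] + 1L])
}

#' Health-sensitive logistic allocation rule
#'
#' Evaluates \eqn{R_h = \lambda \, e^{\gamma H}/(1+e^{\gamma H})}
#' with an overflow-safe sigmoid (stable for \eqn{|\gamma H|} up to at least
#' 1e4).  The result is clamped into the open interval \eqn{(0, \lambda)}
#' so the mathematical range is preserved in floating point.  The sigmoid
#' symmetry \eqn{R(H) + R(-H) = \lambda} holds *exactly* in floating point
#' for \eqn{|\gamma H| \lesssim 36} (beyond that the tail clamp takes over).
#'
#' @param H health index (vectorised).
#' @param params a [logistic_allocation_params()] object.
#' @return allocated resources, strictly inside \eqn{(0, \lambda)}.
#' @examples
#' logistic_allocation(0, logistic_allocation_params(10, 1))       # 5
#' logistic_allocation(log(3), logistic_allocation_params(10, 1))  # 7.5
#' @export
logistic_allocation <- function(H, params) {
  stopifnot(inherits(params, "logistic_allocation_params"))
  lam <- params$lam_total
  x <- params$gamma_sens * H
  # evaluate the minority side q = lam * sigma(-|x|) <= lam/2 and mirror it:
  # the (H, -H) pair then shares the same q, making R(H) + R(-H) = lam exact
  e <- exp(-abs(x))
  q <- lam * (e / (1 + e))
  # quantise q to a multiple of ulp(lam): lam - q is then exact and the
  # (H, -H) pair sums to exactly lam; only the far sigmoid tail (below
  # lam * 2^-53) loses precision to the quantisation
  u <- 2^(floor(log2(lam)) - 52)
  q <- round(q / u) * u
  r <- ifelse(x >= 0, lam - q, q)
  r[x == 0] <- lam / 2
  # keep the open-interval range of the sigmoid in floating point
  pmin(pmax(r, .Machine$double.xmin), lam * (1 - .Machine$double.eps))
}

#' Budget-constrained allocation problem
#'
#' @param individuals non-empty list of [utility_params()] objects.
#' @param budget total resources to allocate, `>= 0`.
#' @param bounds optional per-individual caps (numeric vector, `> 0`).
#' @return object of class `budget_problem`.
#' @export
budget_problem <- function(individuals, budget, bounds = NULL) {
  if (length(individuals) == 0L)
    stop("individual list must be non-empty", call. = FALSE)
  if (!all(vapply(individuals, inherits, TRUE, "utility_params")))
    stop("all individuals must be utility_params objects", call. = FALSE)
  budget <- chk_num1(budget, "budget")
  if (budget < 0) stop("budget must be >= 0", call. = FALSE)
  if (!is.null(bounds)) {
    if (length(bounds) != length(individuals) || any(bounds <= 0))
      stop("bounds must be positive, one per individual", call. = FALSE)
  }
  structure(list(individuals = individuals, budget = budget, bounds = bounds),
            class = "budget_problem")
}

# Resources demanded by one individual at multiplier mu: the R solving
# U'(R) = mu on [0, cap], exploiting monotone-decreasing U' in concave mode.
demand_at_mu <- function(params, mu, cap) {
  if (cap <= 0) return(0)
  mu_cap <- marginal_utility(cap, params)
  if (mu <= mu_cap) return(cap)            # marginal still above mu at the cap
  mu0 <- marginal_utility(min(1e-10, cap / 2), params)
  if (mu >= mu0) return(0)                 # not worth the first unit
  uniroot(function(R) marginal_utility(R, params) - mu,
          lower = min(1e-10, cap / 2), upper = cap, tol = 1e-12)$root
}

#' Maximise total utility under a shared budget
#'
#' Solves \eqn{\max \sum_i U_i(R_i)} subject to \eqn{\sum_i R_i \le B},
#' \eqn{R_i \ge 0} (and optional caps).  When every individual passes
#' [check_diminishing_returns()] on `[0, B]` the problem is concave and is
#' solved by bisection on the shared Lagrange multiplier \eqn{\mu}, inverting
#' each individual's marginal utility; KKT residuals are reported.  Otherwise
#' the solver falls back to a best-of-multistart projected local search and
#' flags the result `non_concave = TRUE` (no global-optimality claim).
#'
#' @param problem a [budget_problem()].
#' @param tol relative tolerance on the budget constraint.
#' @param n_starts multistart count for the non-concave fallback.
#' @param seed seed for the multistart draws (only used when non-concave).
#' @return a list with `R` (per-individual allocation), `U` (per-individual
#'   utilities), `total_utility`, `multiplier`, `kkt_residual`,
#'   `non_concave` flag and `budget_used`.
#' @export
allocate_budget <- function(problem, tol = 1e-9, n_starts = 20L, seed = 1L) {
  stopifnot(inherits(problem, "budget_problem"))
  inds <- problem$individuals
  B <- problem$budget
  n <- length(inds)
  caps <- if (is.null(problem$bounds)) rep(B, n) else pmin(problem$bounds, B)
  if (B == 0) {
    return(list(R = rep(0, n), U = rep(0, n), total_utility = 0,
                multiplier = NA_real_, kkt_residual = 0,
                non_concave = FALSE, budget_used = 0))
  }
  concave <- all(vapply(inds, function(p)
    check_diminishing_returns(p, R_max = B)$ok, TRUE))

  if (concave) {
    total_demand <- function(mu)
      sum(vapply(seq_len(n), function(i) demand_at_mu(inds[[i]], mu, caps[i]),
                 numeric(1)))
    if (total_demand(0) <= B) {
      mu <- 0
    } else {
      # bisection on mu: total demand is non-increasing in mu
      lo <- 0
      hi <- max(vapply(inds, function(p)
        marginal_utility(min(1e-10, B / 2), p), numeric(1)))
      if (!is.finite(hi)) hi <- 1e12   # theta < 1 gives infinite U'(0+)
      while (total_demand(hi) > B) hi <- hi * 10
      for (k in 1:200) {
        mu <- (lo + hi) / 2
        if (total_demand(mu) > B) lo <- mu else hi <- mu
        if (hi - lo < 1e-14 * max(1, hi)) break
      }
      mu <- hi
    }
    R <- vapply(seq_len(n), function(i) demand_at_mu(inds[[i]], mu, caps[i]),
                numeric(1))
    # scale out any residual bisection slack on an active budget
    if (mu > 0 && sum(R) > 0) R <- R * min(1, B / sum(R))
    kkt <- max(vapply(seq_len(n), function(i) {
      mui <- marginal_utility(R[i], inds[[i]])
      if (R[i] > tol * B && R[i] < caps[i] - tol * B) abs(mui - mu)
      else if (R[i] <= tol * B) max(0, mui - mu) else max(0, mu - mui)
    }, numeric(1)))
    U <- vapply(seq_len(n), function(i) utility(R[i], inds[[i]]), numeric(1))
    return(list(R = R, U = U, total_utility = sum(U), multiplier = mu,
                kkt_residual = kkt, non_concave = FALSE, budget_used = sum(R)))
  }

  # non-concave fallback: multistart local search over simplex coordinates
  obj <- function(R) sum(vapply(seq_len(n), function(i)
    utility(R[i], inds[[i]]), numeric(1)))
  project <- function(R) {
    R <- pmin(pmax(R, 0), caps)
    s <- sum(R)
    if (s > B) R <- R * B / s
    R
  }
  best <- NULL; best_val <- -Inf
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  starts <- c(list(project(rep(B / n, n))),
              lapply(seq_len(n_starts - 1L), function(k) {
                w <- rexp(n); project(B * w / sum(w))
              }))
  for (R0 in starts) {
    opt <- stats::optim(R0, function(R) -obj(project(R)),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    Rloc <- project(opt$par)
    v <- obj(Rloc)
    if (v > best_val) { best_val <- v; best <- Rloc }
  }
  U <- vapply(seq_len(n), function(i) utility(best[i], inds[[i]]), numeric(1))
  list(R = best, U = U, total_utility = sum(U), multiplier = NA_real_,
       kkt_residual = NA_real_, non_concave = TRUE, budget_used = sum(best))
}
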