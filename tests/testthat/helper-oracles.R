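# Independent oracles used across the suite. Each is deliberately a
# different route than the implementation it checks.

# Exhaustive grid search for a 3-individual budget problem with strictly
# increasing utilities (full budget spent at the optimum). step is the grid
# resolution; returns allocation and total utility of the best grid point.
grid_search_alloc3 <- function(inds, budget, step = 0.01) {
  g <- seq(0, budget, by = step)
  u1 <- utility(g, inds[[1]])
  u2 <- utility(g, inds[[2]])
  u3 <- utility(g, inds[[3]])
  n <- length(g)
  best_val <- -Inf
  best <- c(0, 0, 0)
  for (i in seq_len(n)) {
    jmax <- n - i + 1L
    j <- seq_len(jmax)
    k <- jmax - j + 1L          # indices with g[i] + g[j] + g[k] = budget
    vals <- u1[i] + u2[j] + u3[k]
    m <- which.max(vals)
    if (vals[m] > best_val) {
      best_val <- vals[m]
      best <- c(g[i], g[j[m]], g[k[m]])
    }
  }
  list(R = best, total_utility = best_val)
}

# Direct GP posterior mean/sd by plain solve() on the full kernel matrix --
# independent of the Cholesky route in impute_short_gaps().
gp_oracle <- function(t_obs, y_obs, t_query, ell, noise_sd, sf2 = var(y_obs)) {
  sf2 <- max(sf2, .Machine$double.eps)
  k <- function(a, b) sf2 * exp(-0.5 * outer(a, b, "-")^2 / ell^2)
  K <- k(t_obs, t_obs)
  diag(K) <- diag(K) + noise_sd^2 + 1e-10 * sf2
  Ks <- k(t_query, t_obs)
  mu0 <- mean(y_obs)
  mu <- mu0 + Ks %*% solve(K, y_obs - mu0)
  v <- pmax(sf2 - diag(Ks %*% solve(K, t(Ks))), 0)
  list(mean = as.numeric(mu), sd = sqrt(v))
}

# Concave, strictly increasing utility draws (theta = delta_u <= 1):
# U = a x / (1 + b x) with x = R^theta is concave-increasing in R.
random_concave_params <- function() {
  th <- runif(1, 0.5, 1)
  utility_params(a = runif(1, 0.5, 2), b = runif(1, 0.1, 1),
                 theta = th, delta_u = th)
}

# Sinusoidal, mutually non-proportional driver set for calibration tests.
calib_drivers <- function(amp = 1) {
  driver_signals(
    S     = function(t) 2 + amp * sin(0.89 * t),
    P     = function(t) 1.5 + amp * cos(1.31 * t),
    E_env = function(t) 1.2 + amp * sin(0.53 * t + 1),
    C_exo = function(t) 2 + amp * cos(0.71 * t)
  )
}

# Synthetic monitoring stream: iid baseline with optional injected joint
# events (activity drop + heart-rate rise), each `dur` points long.
make_joint_stream <- function(n, event_starts = integer(0), dur = 12,
                              act_mu = 50, act_sd = 2, hr_mu = 70,
                              hr_sd = 1.5, effect = 3, seed = 1) {
  set.seed(seed)
  t <- seq_len(n)
  act <- rnorm(n, act_mu, act_sd)
  hr <- rnorm(n, hr_mu, hr_sd)
  for (s in event_starts) {
    idx <- s:min(n, s + dur - 1L)
    act[idx] <- act[idx] - effect * act_sd
    hr[idx] <- hr[idx] + effect * hr_sd
  }
  list(activity = sensor_series(t, act, channel = "activity"),
       heart_rate = sensor_series(t, hr, channel = "heart_rate"))
}
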