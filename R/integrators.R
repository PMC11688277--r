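# Scalar ODE integrators. The package default is fixed-step classical RK4
# with steps taken from the output grid (deterministic, reproducible); the
# adaptive step-doubling variant exists as an independent high-accuracy
# reference and is what the test-suite oracles use.

# One classical RK4 step for scalar dH/dt = f(t, H).
rk4_step <- function(f, t, h, dt) {
  k1 <- f(t, h)
  k2 <- f(t + dt / 2, h + dt * k1 / 2)
  k3 <- f(t + dt / 2, h + dt * k2 / 2)
  k4 <- f(t + dt, h + dt * k3)
  h + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
}

# Integrate f over t_grid with one RK4 step per grid interval.
integrate_rk4 <- function(f, H0, t_grid) {
  n <- length(t_grid)
  H <- numeric(n)
  H[1] <- H0
  for (i in seq_len(n - 1L)) {
    H[i + 1L] <- rk4_step(f, t_grid[i], H[i], t_grid[i + 1L] - t_grid[i])
    if (!is.finite(H[i + 1L]))
      stop("integrator diverged: non-finite H at t = ", t_grid[i + 1L],
           call. = FALSE)
  }
  H
}

# Adaptive RK4 with step doubling and Richardson extrapolation: each grid
# interval is covered with sub-steps whose local error estimate
# |H_two_half_steps - H_one_step| / 15 is kept below tol.  Independent of the
# fixed-step path; used as the reference solution in tests.
integrate_adaptive <- function(f, H0, t_grid, tol = 1e-10) {
  n <- length(t_grid)
  H <- numeric(n)
  H[1] <- H0
  for (i in seq_len(n - 1L)) {
    t <- t_grid[i]
    t_end <- t_grid[i + 1L]
    h <- H[i]
    dt <- (t_end - t) / 4
    while (t < t_end - 1e-14 * max(1, abs(t_end))) {
      dt <- min(dt, t_end - t)
      big   <- rk4_step(f, t, h, dt)
      half  <- rk4_step(f, t, h, dt / 2)
      small <- rk4_step(f, t + dt / 2, half, dt / 2)
      err <- abs(small - big) / 15
      scale <- tol * max(1, abs(h))
      if (err <= scale) {
        # accept, with Richardson-extrapolated 5th-order update
        h <- small + (small - big) / 15
        t <- t + dt
        if (!is.finite(h))
          stop("integrator diverged: non-finite H at t = ", t, call. = FALSE)
        if (err < scale / 32) dt <- dt * 2
      } else {
        dt <- dt / 2
        if (dt < 1e-12 * max(1, abs(t_end)))
          stop("adaptive integrator step underflow at t = ", t, call. = FALSE)
      }
    }
    H[i + 1L] <- h
  }
  H
}
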