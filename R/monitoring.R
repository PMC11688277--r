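# Operational monitoring: Gaussian-process imputation of short sensor gaps
# and the conjunction emergency rule (activity drop + heart-rate rise).

#' Sensor time series with observation mask
#'
#' @param t strictly increasing time grid.
#' @param values signal values (e.g. heart rate in bpm, activity in
#'   counts/epoch); must be finite wherever observed.
#' @param mask logical vector, `TRUE` where the point is observed.
#' @param channel channel name.
#' @return object of class `sensor_series`.
#' @export
sensor_series <- function(t, values, mask = rep(TRUE, length(t)),
                          channel = "signal") {
  if (length(t) != length(values) || length(t) != length(mask))
    stop("t, values and mask must have equal length", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (!is.logical(mask) || anyNA(mask))
    stop("mask must be logical without NA", call. = FALSE)
  if (!all(is.finite(values[mask])))
    stop("observed values must be finite", call. = FALSE)
  structure(list(t = as.numeric(t), values = as.numeric(values),
                 mask = mask, channel = as.character(channel)),
            class = "sensor_series")
}

#' Gap-handling policy for imputation
#'
#' @param max_gap maximum missing-run length (grid points) still treated as a
#'   "short" gap and imputed; longer gaps are left masked. Default 5.
#' @param kernel_scale squared-exponential kernel length-scale (time units).
#' @param noise_sd observation noise standard deviation, `>= 0`.
#' @return object of class `gap_policy`.
#' @export
gap_policy <- function(max_gap = 5L, kernel_scale = 5, noise_sd = 0) {
  if (max_gap < 1L) stop("max_gap must be >= 1", call. = FALSE)
  if (kernel_scale <= 0) stop("kernel_scale must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(max_gap = as.integer(max_gap),
                 kernel_scale = as.numeric(kernel_scale),
                 noise_sd = as.numeric(noise_sd)),
            class = "gap_policy")
}

# Maximal runs of missing points: data.frame(start, end, length) in indices.
gap_runs <- function(mask) {
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

sqexp_kernel <- function(t1, t2, ell) {
  exp(-0.5 * outer(t1, t2, "-")^2 / ell^2)
}

#' Impute short sensor gaps with a Gaussian-process posterior
#'
#' Fills every missing run of length `<= max_gap` with the posterior mean of
#' a squared-exponential-kernel Gaussian process conditioned on *all*
#' observed points (hyperparameters fixed by the policy, not optimised:
#' length-scale `kernel_scale`, signal variance set to the sample variance of
#' the observed points, observation noise `noise_sd`).  Longer gaps are left
#' masked and reported.  Observed points are passed through unchanged.
#'
#' @param series a [sensor_series()] with at least 2 observed points.
#' @param policy a [gap_policy()].
#' @return a list with `series` (the completed [sensor_series()]; the mask is
#'   `TRUE` also at imputed points), `sd` (per-point predictive standard
#'   deviation: 0 at observed points, `NA` at still-missing points) and
#'   `long_gaps` (data.frame of untouched gaps with `start`, `end`,
#'   `length`).
#' @export
impute_short_gaps <- function(series, policy) {
  stopifnot(inherits(series, "sensor_series"), inherits(policy, "gap_policy"))
  obs <- series$mask
  if (sum(obs) < 2L)
    stop("need at least 2 observed points to impute", call. = FALSE)
  runs <- gap_runs(obs)
  short <- runs[runs$length <= policy$max_gap, , drop = FALSE]
  long <- runs[runs$length > policy$max_gap, , drop = FALSE]
  out_values <- series$values
  out_mask <- series$mask
  psd <- ifelse(obs, 0, NA_real_)
  if (nrow(short) > 0L) {
    t_obs <- series$t[obs]
    y_obs <- series$values[obs]
    mu0 <- mean(y_obs)
    sf2 <- max(var(y_obs), .Machine$double.eps)
    idx_new <- unlist(mapply(seq, short$start, short$end, SIMPLIFY = FALSE))
    t_new <- series$t[idx_new]
    K <- sf2 * sqexp_kernel(t_obs, t_obs, policy$kernel_scale)
    diag(K) <- diag(K) + policy$noise_sd^2 + 1e-10 * sf2
    Ks <- sf2 * sqexp_kernel(t_new, t_obs, policy$kernel_scale)
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), y_obs - mu0))
    mu_post <- mu0 + as.numeric(Ks %*% alpha)
    V <- forwardsolve(t(L), t(Ks))
    var_post <- pmax(sf2 - colSums(V^2), 0)
    out_values[idx_new] <- mu_post
    out_mask[idx_new] <- TRUE
    psd[idx_new] <- sqrt(var_post)
  }
  list(
    series = sensor_series(series$t, out_values, out_mask, series$channel),
    sd = psd,
    long_gaps = long
  )
}

#' Rolling z-scores against a trailing baseline
#'
#' \eqn{z_t = (x_t - \mathrm{mean}_W)/\mathrm{sd}_W} where \eqn{W} is the
#' trailing window of `baseline_window` points ending immediately before
#' `t`.  Points without a full baseline get `NA`; a zero-variance baseline
#' yields `NA` at that point with one warning.
#'
#' @param series a [sensor_series()].
#' @param baseline_window trailing window length in grid points, `>= 3`.
#' @return numeric vector of z-scores aligned with `series$t`.
#' @export
rolling_zscores <- function(series, baseline_window = 48L) {
  stopifnot(inherits(series, "sensor_series"))
  w <- as.integer(baseline_window)
  if (w < 3L) stop("baseline_window must be >= 3", call. = FALSE)
  x <- ifelse(series$mask, series$values, NA_real_)
  n <- length(x)
  z <- rep(NA_real_, n)
  zero_var <- FALSE
  if (n > w && !anyNA(x)) {
    # fully-observed fast path: running moments via linear filters
    sums <- stats::filter(x, rep(1, w), sides = 1)
    sqs <- stats::filter(x^2, rep(1, w), sides = 1)
    i <- (w + 1L):n
    mb <- as.numeric(sums[i - 1L]) / w
    vb <- pmax((as.numeric(sqs[i - 1L]) - w * mb^2) / (w - 1), 0)
    s <- sqrt(vb)
    zero_var <- any(s == 0)
    z[i] <- ifelse(s == 0, NA_real_, (x[i] - mb) / s)
  } else if (n > w) {
    for (i in (w + 1L):n) {
      base <- x[(i - w):(i - 1L)]
      base <- base[!is.na(base)]
      if (length(base) < 3L || is.na(x[i])) next
      s <- sd(base)
      if (s == 0) { zero_var <- TRUE; next }
      z[i] <- (x[i] - mean(base)) / s
    }
  }
  if (zero_var)
    warning("zero baseline variance: z-score undefined at some points",
            call. = FALSE)
  z
}

#' Emergency alert rule
#'
#' Configuration of the conjunction rule: an emergency window is one where
#' the window-averaged activity z-score falls below `z_drop` *and* the
#' window-averaged heart-rate z-score rises above `z_rise` simultaneously.
#' Both thresholds and the window are clinician-configurable.
#'
#' @param window detection window length in grid points, `>= 2`.
#' @param z_drop activity z-score threshold, `<= 0`.
#' @param z_rise heart-rate z-score threshold, `>= 0`.
#' @param escalation_levels strictly increasing severity thresholds applied
#'   to the maximum absolute windowed z-score of an event.
#' @param baseline_window trailing baseline length for [rolling_zscores()].
#' @return object of class `alert_rule`.
#' @export
alert_rule <- function(window = 12L, z_drop = -2, z_rise = 2,
                       escalation_levels = c(2, 3, 4),
                       baseline_window = 48L) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  if (z_drop > 0) stop("z_drop must be <= 0", call. = FALSE)
  if (z_rise < 0) stop("z_rise must be >= 0", call. = FALSE)
  if (is.unsorted(escalation_levels, strictly = TRUE))
    stop("escalation_levels must be strictly increasing", call. = FALSE)
  structure(list(window = window, z_drop = as.numeric(z_drop),
                 z_rise = as.numeric(z_rise),
                 escalation_levels = as.numeric(escalation_levels),
                 baseline_window = as.integer(baseline_window)),
            class = "alert_rule")
}

# Windowed z-scores: for the window of w points ending at i, the statistic is
# (mean(window) - mean(baseline)) / sd(baseline), with the baseline the bw
# points ending immediately before the window starts. Keeping the baseline
# outside the window avoids self-contamination during an event. Windows or
# baselines containing missing points give NA.
windowed_zscores <- function(series, w, bw) {
  x <- ifelse(series$mask, series$values, NA_real_)
  n <- length(x)
  z <- rep(NA_real_, n)
  if (n < w + bw) return(z)
  mw <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
  sb <- as.numeric(stats::filter(x, rep(1, bw), sides = 1))
  qb <- as.numeric(stats::filter(x^2, rep(1, bw), sides = 1))
  i <- (w + bw):n
  mb <- sb[i - w] / bw
  vb <- pmax((qb[i - w] - bw * mb^2) / (bw - 1), 0)
  s <- sqrt(vb)
  z[i] <- ifelse(is.na(s) | s == 0, NA_real_, (mw[i] - mb) / s)
  z
}

#' Detect emergencies: simultaneous activity drop and heart-rate rise
#'
#' For every sliding window of `rule$window` points, each channel's windowed
#' z-score is the window mean standardised against the trailing baseline of
#' `rule$baseline_window` points ending immediately *before* the window (so
#' an ongoing event cannot contaminate its own baseline).  A window position
#' qualifies when the windowed activity z is `<= z_drop` while the windowed
#' heart-rate z is `>= z_rise`.  Qualifying positions that overlap, or are
#' separated by fewer than `window/2` points, are merged into a single alert
#' event; severity is the number of escalation thresholds not exceeding the
#' maximum absolute windowed z-score within the event.
#'
#' The rule is a strict conjunction: a drop-only or rise-only anomaly never
#' triggers an event.
#'
#' @param activity,heart_rate [sensor_series()] objects on the *same* grid.
#' @param rule an [alert_rule()].
#' @return a data.frame of alert events with columns `t_start`, `t_end`,
#'   `severity`, `max_abs_z`, `z_activity`, `z_heart_rate` (the extreme
#'   windowed z-scores in the event).  The attribute `n_qualifying` carries
#'   the raw count of qualifying window positions before merging (monotone
#'   in the thresholds).
#' @export
detect_emergency <- function(activity, heart_rate, rule = alert_rule()) {
  stopifnot(inherits(activity, "sensor_series"),
            inherits(heart_rate, "sensor_series"),
            inherits(rule, "alert_rule"))
  if (length(activity$t) != length(heart_rate$t) ||
      any(activity$t != heart_rate$t))
    stop("activity and heart-rate series must share the same time grid",
         call. = FALSE)
  za <- windowed_zscores(activity, rule$window, rule$baseline_window)
  zh <- windowed_zscores(heart_rate, rule$window, rule$baseline_window)
  qual <- which(!is.na(za) & !is.na(zh) &
                  za <= rule$z_drop & zh >= rule$z_rise)
  events <- list()
  if (length(qual) > 0L) {
    # merge qualifying window positions closer than window/2 apart
    brk <- which(diff(qual) >= rule$window / 2)
    grp_start <- c(1L, brk + 1L)
    grp_end <- c(brk, length(qual))
    t <- activity$t
    dt <- if (length(t) > 1) stats::median(diff(t)) else 1
    for (g in seq_along(grp_start)) {
      idx <- qual[grp_start[g]:grp_end[g]]
      # window ending at idx spans [idx-window+1, idx]
      i0 <- max(1L, min(idx) - rule$window + 1L)
      i1 <- max(idx)
      mz <- max(abs(c(za[idx], zh[idx])))
      t_end <- if (i1 > i0) t[i1] else t[i1] + dt
      events[[g]] <- data.frame(
        t_start = t[i0], t_end = t_end,
        severity = max(1L, sum(rule$escalation_levels <= mz)),
        max_abs_z = mz,
        z_activity = min(za[idx]),
        z_heart_rate = max(zh[idx]))
    }
  }
  out <- if (length(events)) do.call(rbind, events)
  else data.frame(t_start = numeric(0), t_end = numeric(0),
                  severity = integer(0), max_abs_z = numeric(0),
                  z_activity = numeric(0), z_heart_rate = numeric(0))
  attr(out, "n_qualifying") <- length(qual)
  out
}
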