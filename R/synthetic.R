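# Synthetic world: driver-signal processes, scenario cohorts with directional
# arm contrasts, sensor-gap injection, and the bundled market-survey tables.

#' Derive a per-stream seed from the global seed
#'
#' Counter/hash scheme: the stream label is hashed (base-31 polynomial over
#' its UTF-8 bytes, mod 1e9+7) and added to the global seed modulo
#' `.Machine$integer.max`.  Because each stream's seed depends only on
#' `(seed, label)`, adding a new generator never perturbs existing streams.
#'
#' @param seed global integer seed.
#' @param stream character label of the stream.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(as.numeric(seed)) + h) %% .Machine$integer.max)
}

# Run fn with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# One generated series for a process config on t_grid.
gen_process <- function(t_grid, cfg, seed) {
  proc <- cfg$process
  if (is.null(proc)) stop("process config needs a 'process' name", call. = FALSE)
  n <- length(t_grid)
  if (proc == "constant") {
    rep(chk_num1(cfg$value, "value"), n)
  } else if (proc == "sinusoid") {
    mean_ <- cfg$mean %||% 0; amp <- cfg$amplitude %||% 1
    period <- cfg$period %||% 10; phase <- cfg$phase %||% 0
    noise <- cfg$noise_sd %||% 0
    base <- mean_ + amp * sin(2 * pi * t_grid / period + phase)
    if (noise > 0) base <- base + with_seed(seed, function() rnorm(n, 0, noise))
    base
  } else if (proc == "mean_reverting") {
    # exact AR(1) discretisation of an Ornstein-Uhlenbeck process:
    # stationary sd = sd / sqrt(2 * rate); initialised at stationarity
    rate <- chk_num1(cfg$rate, "rate"); mu <- cfg$mean %||% 0
    s <- chk_num1(cfg$sd, "sd")
    if (rate <= 0) stop("mean_reverting 'rate' must be > 0", call. = FALSE)
    sd_stat <- s / sqrt(2 * rate)
    with_seed(seed, function() {
      x <- numeric(n)
      x[1] <- mu + sd_stat * rnorm(1)
      if (n > 1) for (i in 2:n) {
        phi <- exp(-rate * (t_grid[i] - t_grid[i - 1]))
        x[i] <- mu + phi * (x[i - 1] - mu) +
          sd_stat * sqrt(1 - phi^2) * rnorm(1)
      }
      x
    })
  } else {
    stop("unknown process '", proc, "'", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate driver signals from per-channel process configurations
#'
#' Each channel of the returned [driver_signals()] is generated independently
#' with its own derived seed (see [derive_seed()]), so the result is a pure
#' function of `(spec, seed)`.
#'
#' @param t_grid strictly increasing time grid.
#' @param spec named list with entries among `S`, `P`, `E_env`, `C_exo`,
#'   `R_exo`; each a list with a `process` name (`"constant"`, `"sinusoid"`
#'   or `"mean_reverting"`) and its parameters.
#' @param seed global integer seed.
#' @return a [driver_signals()] object backed by dense series on `t_grid`.
#' @export
generate_drivers <- function(t_grid, spec, seed = 1L) {
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  channels <- c("S", "P", "E_env", "C_exo", "R_exo")
  unknown <- setdiff(names(spec), channels)
  if (length(unknown))
    stop("unknown driver channels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (ch in channels) {
    if (!is.null(spec[[ch]])) {
      v <- gen_process(t_grid, spec[[ch]], derive_seed(seed, ch))
      args[[ch]] <- data.frame(t = t_grid, value = v)
    }
  }
  do.call(driver_signals, args)
}

# ---- scenario cohorts --------------------------------------------------------

# Baseline prior set: list of c(mean, sd, min, max) per parameter. Truncation
# keeps every draw admissible for all downstream validators.
base_priors <- function() {
  list(
    alpha1  = c(0.30, 0.05, 0, Inf),
    alpha2  = c(0.20, 0.05, 0, Inf),
    alpha3  = c(0.10, 0.05, 0, Inf),
    beta    = c(0.20, 0.05, 0, Inf),
    S       = c(1.00, 0.20, 0, 2),
    P       = c(0.50, 0.20, 0, 2),
    E_env   = c(0.50, 0.20, 0, 2),
    C_exo   = c(1.00, 0.20, 0.05, Inf),
    H0      = c(0.00, 0.50, -3, 3),
    alpha_r = c(1.00, 0.10, 0.1, Inf),
    kappa   = c(0.50, 0.10, 0, Inf),
    lam_total = c(10.0, 1.0, 0.5, Inf),
    gamma_sens = c(-1.0, 0.10, -Inf, -0.1),
    C0      = c(1.00, 0.20, 0, Inf),
    delta_sc = c(0.20, 0.08, 0, 0.4),
    eta     = c(0.50, 0.10, 0, Inf)
  )
}

# Directional contrast dictionary: per scenario, per arm, shifts expressed in
# prior standard deviations (default effect size 0.5 sd). E_env is an
# environmental favourability index in the generator (higher = better),
# matching its positive gain alpha3 in the linear driver model.
scenario_catalog <- function(effect = 0.5) {
  e <- effect
  list(
    urban_rural = list(
      urban = list(n = 500, shift = c(beta = e, E_env = -e)),
      rural = list(n = 500, shift = c())
    ),
    income = list(
      high_income = list(n = 500, shift = c()),
      low_income  = list(n = 500, shift = c(beta = e, H0 = -e))
    ),
    lifestyle = list(
      active    = list(n = 500, shift = c(alpha1 = e, alpha2 = e, alpha3 = e)),
      sedentary = list(n = 500, shift = c())
    ),
    diet = list(
      balanced       = list(n = 300, shift = c(beta = -e)),
      high_fat_sugar = list(n = 300, shift = c(beta = e)),
      vegetarian     = list(n = 300, shift = c())
    ),
    social = list(
      high_social   = list(n = 400, shift = c(S = e, P = e)),
      medium_social = list(n = 400, shift = c()),
      low_social    = list(n = 400, shift = c(S = -e, P = -e))
    ),
    pollution = list(
      high_pollution = list(n = 500, shift = c(E_env = -e, beta = e)),
      low_pollution  = list(n = 500, shift = c())
    )
  )
}

#' Scenario specification for cohort generation
#'
#' The six shipped scenarios contrast urban/rural residence, income,
#' lifestyle activity, dietary pattern, social activity and pollution
#' exposure.  Arm contrasts are encoded as shifts (in prior standard
#' deviations) of the relevant parameters; the default effect size is 0.5 sd
#' and all directions and magnitudes are configurable through `arms`.
#'
#' @param name scenario name; one of `"urban_rural"`, `"income"`,
#'   `"lifestyle"`, `"diet"`, `"social"`, `"pollution"`.
#' @param arms optional custom arm list: named list of
#'   `list(n = <count>, shift = c(param = sd_units, ...))`; defaults to the
#'   shipped catalogue for `name`.
#' @param seed integer seed.
#' @param effect default effect size in prior sd units for catalogue arms.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, arms = NULL, seed = 1L, effect = 0.5) {
  catalog <- scenario_catalog(effect)
  if (is.null(arms)) {
    if (!name %in% names(catalog))
      stop("unknown scenario '", name, "'; shipped scenarios: ",
           paste(names(catalog), collapse = ", "), call. = FALSE)
    arms <- catalog[[name]]
  }
  for (a in names(arms)) {
    if (is.null(arms[[a]]$n) || arms[[a]]$n <= 0)
      stop("arm '", a, "' must have n > 0", call. = FALSE)
    bad <- setdiff(names(arms[[a]]$shift), names(base_priors()))
    if (length(bad))
      stop("arm '", a, "' shifts unknown parameters: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, arms = arms, seed = as.integer(seed)),
            class = "scenario_spec")
}

draw_truncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort for a scenario
#'
#' Draws per-individual parameters from the arm priors (truncated normals,
#' shifted by the arm's directional contrasts), then simulates each
#' individual's health trajectory under the linear driver model with constant
#' personal drivers.  Draws are a pure function of `(spec, seed)`.
#'
#' @param spec a [scenario_spec()].
#' @param t_grid time grid for the per-individual trajectories.
#' @param simulate simulate trajectories (default `TRUE`); when `FALSE` only
#'   parameters are drawn.
#' @param include_streams also synthesise activity and heart-rate sensor
#'   streams from each trajectory (default `FALSE`; heart rate in bpm around
#'   70, activity in counts/epoch around 50, both responding to `H`).
#' @return object of class `synthetic_cohort`: a list with `individuals`
#'   (a data.frame of ids, arms, parameters, and `H_end`/`H_mean` summaries
#'   when simulated), `trajectories` (list of [health_state()] or `NULL`)
#'   and `streams` (list or `NULL`).
#' @export
generate_population <- function(spec, t_grid = seq(0, 30, by = 1),
                                simulate = TRUE, include_streams = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  priors <- base_priors()
  # validate prior admissibility before any draw
  for (a in names(spec$arms)) {
    sh <- spec$arms[[a]]$shift
    for (p in names(sh)) {
      pr <- priors[[p]]
      m <- pr[1] + sh[[p]] * pr[2]
      if (m < pr[3] - 3 * pr[2] || m > pr[4] + 3 * pr[2])
        stop("arm '", a, "': shifted prior for '", p,
             "' is inadmissible", call. = FALSE)
    }
  }
  rows <- list()
  trajectories <- list()
  streams <- list()
  id0 <- 0L
  for (a in names(spec$arms)) {
    arm <- spec$arms[[a]]
    n <- arm$n
    arm_seed <- derive_seed(spec$seed, paste0("arm:", a))
    draws <- with_seed(arm_seed, function() {
      out <- list()
      for (p in names(priors)) {
        pr <- priors[[p]]
        sh <- if (p %in% names(arm$shift)) arm$shift[[p]] else 0
        out[[p]] <- draw_truncnorm(n, pr[1] + sh * pr[2], pr[2], pr[3], pr[4])
      }
      as.data.frame(out)
    })
    draws$id <- sprintf("%s_%04d", a, seq_len(n))
    draws$arm <- a
    if (simulate) {
      H_end <- numeric(n); H_mean <- numeric(n)
      for (i in seq_len(n)) {
        g <- draws$alpha1[i] * draws$S[i] + draws$alpha2[i] * draws$P[i] +
          draws$alpha3[i] * draws$E_env[i] - draws$beta[i] * draws$C_exo[i]
        # linear model with constant drivers: exact trajectory H0 + g*t
        H <- draws$H0[i] + g * t_grid
        trajectories[[id0 + i]] <- health_state(t_grid, H)
        H_end[i] <- H[length(H)]
        H_mean[i] <- mean(H)
        if (include_streams) {
          s_seed <- derive_seed(spec$seed, paste0("stream:", draws$id[i]))
          streams[[id0 + i]] <- with_seed(s_seed, function() list(
            activity = sensor_series(
              t_grid, 50 + 5 * H + rnorm(length(H), 0, 2),
              channel = "activity"),
            heart_rate = sensor_series(
              t_grid, 70 - 3 * H + rnorm(length(H), 0, 1.5),
              channel = "heart_rate")
          ))
        }
      }
      draws$H_end <- H_end
      draws$H_mean <- H_mean
    }
    rows[[a]] <- draws
    id0 <- id0 + n
  }
  individuals <- do.call(rbind, rows)
  rownames(individuals) <- NULL
  structure(list(
    scenario = spec$name,
    individuals = individuals,
    trajectories = if (simulate) trajectories else NULL,
    streams = if (include_streams) streams else NULL,
    seed = spec$seed
  ), class = "synthetic_cohort")
}

#' Inject missingness into a sensor series
#'
#' Marks points as missing either uniformly at random (`"random"`: exactly
#' `round(rate * n)` points, so the observed count is within one point of
#' `(1 - rate) * n`) or as contiguous bursts of length at most `max_burst`
#' (`"burst"`; bursts are placed with at least one observed point between
#' them so no merged run exceeds `max_burst`).  Original values are retained
#' under the mask for later imputation scoring.
#'
#' @param series a [sensor_series()].
#' @param mechanism `"random"` or `"burst"`.
#' @param rate missing fraction in `[0, 1)`.
#' @param max_burst maximum burst length for the burst mechanism.
#' @param seed integer seed.
#' @return the series with an updated mask.
#' @export
inject_missingness <- function(series, mechanism = c("random", "burst"),
                               rate, max_burst = 5L, seed = 1L) {
  stopifnot(inherits(series, "sensor_series"))
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)", call. = FALSE)
  n <- length(series$t)
  target <- round(rate * n)
  mask <- series$mask
  if (target > 0) {
    if (mechanism == "random") {
      idx <- with_seed(seed, function() sample.int(n, target))
      mask[idx] <- FALSE
    } else {
      mask <- with_seed(seed, function() {
        m <- mask
        missing_ct <- 0L
        attempts <- 0L
        while (missing_ct < target && attempts < 50L * n) {
          attempts <- attempts + 1L
          len <- min(sample.int(max_burst, 1), target - missing_ct)
          s <- sample.int(n - len + 1L, 1)
          span <- max(1L, s - 1L):min(n, s + len)
          if (all(m[span])) {           # keep bursts separated
            m[s:(s + len - 1L)] <- FALSE
            missing_ct <- missing_ct + len
          }
        }
        m
      })
    }
  }
  sensor_series(series$t, series$values, mask, series$channel)
}

# ---- market-survey fixtures --------------------------------------------------

market_fixture_info <- list(
  features = list(file = "market_features.csv",
                  md5 = NULL),  # filled at load from bundled checksum file
  conditions = list(file = "market_conditions.csv", md5 = NULL)
)

#' Load a bundled market-survey table
#'
#' Returns one of the two market-research tables shipped with the package:
#' `"features"` (feature importance, current availability, technical
#' difficulty on a 1-5 scale, expected 5-year coverage) or `"conditions"`
#' (health-condition population share, service coverage, mortality and
#' personalisation needs).  Cell values are validated (percentages in
#' \[0, 100\], difficulty in \[1, 5\]) and the file checksum is verified
#' against the bundled manifest.
#'
#' @param which `"features"` or `"conditions"`.
#' @return a data.frame of class `market_table`.
#' @export
load_market_table <- function(which = c("features", "conditions")) {
  which <- match.arg(which)
  info <- market_fixture_info[[which]]
  path <- system.file("extdata", info$file, package = "eldersim")
  if (path == "" || !file.exists(path))
    stop("market fixture '", info$file, "' is missing from the installation",
         call. = FALSE)
  sums <- read.csv(system.file("extdata", "fixture_checksums.csv",
                               package = "eldersim"), stringsAsFactors = FALSE)
  expected <- sums$md5[sums$file == info$file]
  actual <- unname(tools::md5sum(path))
  if (length(expected) == 1L && actual != expected)
    stop("market fixture '", info$file, "' is corrupt: md5 ", actual,
         " != expected ", expected, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pct_cols <- setdiff(names(tab)[vapply(tab, is.numeric, TRUE)],
                      "technical_difficulty")
  for (cn in pct_cols) {
    if (any(tab[[cn]] < 0 | tab[[cn]] > 100))
      stop("fixture '", info$file, "': column '", cn,
           "' outside [0, 100]", call. = FALSE)
  }
  if ("technical_difficulty" %in% names(tab) &&
      any(tab$technical_difficulty < 1 | tab$technical_difficulty > 5))
    stop("fixture '", info$file, "': difficulty outside [1, 5]", call. = FALSE)
  structure(tab, class = c("market_table", "data.frame"))
}

#' Feature gap report: importance minus availability
#'
#' Computes `gap = importance - current availability` per feature and sorts
#' descending by gap (ties broken by feature label), quantifying the
#' functional gaps between what users value and what the market offers.
#'
#' @param table the `"features"` [load_market_table()] table (or any
#'   data.frame with `feature`, `importance_pct`, `availability_pct`).
#' @return the table with a `gap` column, sorted by decreasing gap.
#' @export
feature_gap_report <- function(table = load_market_table("features")) {
  need <- c("feature", "importance_pct", "availability_pct")
  if (!all(need %in% names(table)))
    stop("feature table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  table$gap <- table$importance_pct - table$availability_pct
  out <- table[order(-table$gap, table$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
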