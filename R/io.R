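# Readers/writers for all file artifacts. Fixed CSV dialect: UTF-8, comma
# separator, header row, '.' decimal, numeric time column.

#' Write / read a health trajectory as CSV
#'
#' Columns `t`, `H`.
#'
#' @param trajectory a [health_state()].
#' @param path file path.
#' @return `read_trajectory_csv()` returns a [health_state()].
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "health_state"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("t", "H") %in% names(df)))
    stop("trajectory CSV needs columns 't' and 'H'", call. = FALSE)
  health_state(df$t, df$H)
}

#' Write / read a driver-signal table as CSV
#'
#' Long format with columns `channel`, `t`, `value`; reading returns a
#' [driver_signals()] with one dense series per channel present.
#'
#' @param drivers a [driver_signals()] object backed by series, or a
#'   data.frame in long format.
#' @param t_grid grid on which function-backed channels are sampled.
#' @param path file path.
#' @export
write_drivers_csv <- function(drivers, t_grid, path) {
  stopifnot(is_driver_signals(drivers))
  rows <- list()
  for (ch in c("S", "P", "E_env", "C_exo", "R_exo")) {
    if (!is.null(drivers[[ch]]))
      rows[[ch]] <- data.frame(channel = ch, t = t_grid,
                               value = drivers[[ch]](t_grid))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_drivers_csv
#' @export
read_drivers_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("channel", "t", "value") %in% names(df)))
    stop("drivers CSV needs columns 'channel', 't', 'value'", call. = FALSE)
  args <- list()
  for (ch in unique(df$channel)) {
    sub <- df[df$channel == ch, c("t", "value")]
    args[[ch]] <- sub[order(sub$t), ]
  }
  do.call(driver_signals, args)
}

#' Write / read a sensor series as CSV
#'
#' Columns `t`, `value`, `observed_flag` (0/1).
#'
#' @param series a [sensor_series()].
#' @param path file path.
#' @param channel channel name used when reading.
#' @export
write_sensor_csv <- function(series, path) {
  stopifnot(inherits(series, "sensor_series"))
  write.csv(data.frame(t = series$t, value = series$values,
                       observed_flag = as.integer(series$mask)),
            path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path, channel = "signal") {
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("t", "value", "observed_flag") %in% names(df)))
    stop("sensor CSV needs columns 't', 'value', 'observed_flag'",
         call. = FALSE)
  sensor_series(df$t, df$value, df$observed_flag == 1L, channel)
}

#' Write alert events as JSON lines
#'
#' One JSON object per event with fields `t_start`, `t_end`, `severity` and
#' the z-score evidence.
#'
#' @param events the data.frame returned by [detect_emergency()].
#' @param path file path.
#' @export
write_alerts_jsonl <- function(events, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(events) > 0) for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_alerts_jsonl
#' @export
read_alerts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      severity = integer(0)))
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l))))
}

#' Write / read a parameter list as JSON
#'
#' @param params a named list (classes are dropped on write).
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write a run manifest with input/output checksums
#'
#' The manifest records the command, seed, package version and the md5 of
#' every input and output file.  It contains no timestamps, so identical
#' runs produce byte-identical manifests.
#'
#' @param path manifest path.
#' @param command subcommand name.
#' @param seed seed used.
#' @param inputs,outputs character vectors of file paths.
#' @export
write_manifest <- function(path, command, seed, inputs = character(0),
                           outputs = character(0)) {
  checksum <- function(files) {
    files <- files[file.exists(files)]
    if (length(files) == 0) return(setNames(list(), character(0)))
    as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  }
  manifest <- list(
    command = command,
    seed = seed,
    package = "eldersim",
    version = as.character(utils::packageVersion("eldersim")),
    inputs = checksum(inputs),
    outputs = checksum(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a cohort's individual table as CSV
#'
#' @param cohort a `synthetic_cohort` from [generate_population()].
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write.csv(cohort$individuals, path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
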