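# Driver-signal handling: signals may be supplied as constants, dense series
# or callables; internally everything becomes a function of time.

#' Coerce a signal specification to a function of time
#'
#' Accepted forms:
#' * a single finite numeric — constant signal;
#' * a two-column `data.frame` (columns `t`, `value`) — linear interpolation
#'   between grid points, constant extrapolation beyond the ends;
#' * a function of one argument — used as-is.
#'
#' @param x signal specification.
#' @param name label used in error messages.
#' @return a vectorised function `f(t)`.
#' @export
as_signal <- function(x, name = deparse(substitute(x))) {
  if (is.null(x)) return(NULL)
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x)) stop("signal '", name, "' must be finite", call. = FALSE)
    v <- as.numeric(x)
    return(function(t) rep(v, length(t)))
  }
  if (is.data.frame(x)) {
    if (!all(c("t", "value") %in% names(x)))
      stop("signal '", name, "' data.frame needs columns 't' and 'value'",
           call. = FALSE)
    if (is.unsorted(x$t, strictly = TRUE))
      stop("signal '", name, "': t must be strictly increasing", call. = FALSE)
    if (!all(is.finite(x$value)))
      stop("signal '", name, "': values must be finite", call. = FALSE)
    return(approxfun(x$t, x$value, rule = 2))
  }
  stop("signal '", name, "' must be a constant, a (t,value) data.frame, ",
       "or a function", call. = FALSE)
}

#' Bundle of exogenous driver signals
#'
#' Holds the driver channels of the health-state models: social support
#' `S(t)`, psychological state `P(t)`, environmental exposure `E_env(t)`, and
#' the optional exogenous behaviour-cost `C_exo(t)` and resource `R_exo(t)`
#' channels.  `E_env` is named to avoid the clash with total benefit `E(T)`
#' in the economics layer.
#'
#' @param S,P,E_env,C_exo,R_exo signal specifications accepted by
#'   [as_signal()]; `C_exo` and `R_exo` may be `NULL`.
#' @return an object of class `driver_signals`: a list of functions of time.
#' @examples
#' drv <- driver_signals(S = 1, P = 0.5, E_env = function(t) sin(t), C_exo = 2)
#' drv$S(0:3)
#' @export
driver_signals <- function(S = 0, P = 0, E_env = 0, C_exo = NULL, R_exo = NULL) {
  obj <- list(
    S     = as_signal(S, "S"),
    P     = as_signal(P, "P"),
    E_env = as_signal(E_env, "E_env"),
    C_exo = as_signal(C_exo, "C_exo"),
    R_exo = as_signal(R_exo, "R_exo")
  )
  structure(obj, class = "driver_signals")
}

is_driver_signals <- function(x) inherits(x, "driver_signals")

# Evaluate one channel, failing clearly when the channel is absent.
signal_at <- function(drivers, channel, t) {
  f <- drivers[[channel]]
  if (is.null(f))
    stop("driver signal '", channel, "' is required but absent", call. = FALSE)
  f(t)
}
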