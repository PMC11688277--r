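# Economics layer: social-capital cost modulation, weighted benefit/cost
# aggregates, cost-benefit ratio and scenario comparison.

#' Social-capital modulated behaviour cost
#'
#' Evaluates \eqn{C = C_0 \,(1 - \delta S_c / (1 + \eta R_m))}: the baseline
#' health-behaviour cost `C0` is reduced by social-capital support `Sc`, with
#' the reduction damped by resource input `Rm`.  Inputs for which the offset
#' term exceeds 1 (cost would go negative) raise an admissibility error
#' rather than being clamped: a negative cost signals misconfiguration.
#'
#' @param Sc social-capital support, `>= 0` (vectorised).
#' @param Rm social-capital resource input, `>= 0` (vectorised).
#' @param params a [social_cost_params()] object.
#' @return behaviour cost in `[0, C0]`.
#' @examples
#' behavior_cost(1, 1, social_cost_params(C0 = 10, delta_sc = 0.5, eta = 1)) # 7.5
#' @export
behavior_cost <- function(Sc, Rm, params) {
  stopifnot(inherits(params, "social_cost_params"))
  if (any(Sc < 0) || any(Rm < 0))
    stop("Sc and Rm must be >= 0", call. = FALSE)
  ratio <- params$delta_sc * Sc / (1 + params$eta * Rm)
  bad <- ratio > 1 + 1e-12
  if (any(bad)) {
    i <- which(bad)[1]
    stop("inadmissible cost parameters: delta_sc*Sc/(1+eta*Rm) = ",
         format(ratio[i]), " > 1 (Sc = ", Sc[i], ", Rm = ", Rm[i],
         "); cost would be negative", call. = FALSE)
  }
  params$C0 * (1 - pmin(ratio, 1))
}

#' Weighted benefit components
#'
#' Health, social and economic benefit components with non-negative weights.
#' Weights are not required to sum to 1; see [normalize_weights()].
#'
#' @param E_h,E_s,E_e health, social and economic benefit components.
#' @param w_h,w_s,w_e non-negative weights.
#' @return object of class `benefit_components`.
#' @export
benefit_components <- function(E_h, E_s, E_e, w_h = 1, w_s = 1, w_e = 1) {
  vals <- vapply(list(E_h = E_h, E_s = E_s, E_e = E_e,
                      w_h = w_h, w_s = w_s, w_e = w_e),
                 chk_num1, numeric(1), nm = "benefit component")
  if (any(vals[c("w_h", "w_s", "w_e")] < 0))
    stop("weights must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "benefit_components")
}

#' Weighted cost components
#'
#' Direct, operating and maintenance costs with non-negative weights.
#'
#' @param C_d,C_o,C_m direct, operating and maintenance costs, `>= 0`.
#' @param w_d,w_o,w_m non-negative weights.
#' @return object of class `cost_components`.
#' @export
cost_components <- function(C_d, C_o, C_m, w_d = 1, w_o = 1, w_m = 1) {
  vals <- vapply(list(C_d = C_d, C_o = C_o, C_m = C_m,
                      w_d = w_d, w_o = w_o, w_m = w_m),
                 chk_num1, numeric(1), nm = "cost component")
  if (any(vals[c("C_d", "C_o", "C_m")] < 0))
    stop("costs must be >= 0", call. = FALSE)
  if (any(vals[c("w_d", "w_o", "w_m")] < 0))
    stop("weights must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "cost_components")
}

#' Total weighted benefit
#'
#' \eqn{E(T) = w_h E_h + w_s E_s + w_e E_e}.
#'
#' @param bc a [benefit_components()] object.
#' @return the weighted total benefit.
#' @export
total_benefit <- function(bc) {
  stopifnot(inherits(bc, "benefit_components"))
  bc$w_h * bc$E_h + bc$w_s * bc$E_s + bc$w_e * bc$E_e
}

#' Total weighted cost
#'
#' \eqn{B(T) = w_d C_d + w_o C_o + w_m C_m}.
#'
#' @param cc a [cost_components()] object.
#' @return the weighted total cost.
#' @export
total_cost <- function(cc) {
  stopifnot(inherits(cc, "cost_components"))
  cc$w_d * cc$C_d + cc$w_o * cc$C_o + cc$w_m * cc$C_m
}

#' Cost-benefit ratio
#'
#' \eqn{CBR = E(T) / B(T)}.  A non-positive weighted cost is reported as an
#' error rather than returned as `Inf`.
#'
#' @param benefit total weighted benefit.
#' @param cost total weighted cost, `> 0`.
#' @return the ratio `benefit / cost`.
#' @export
cbr <- function(benefit, cost) {
  benefit <- chk_num1(benefit, "benefit")
  cost <- chk_num1(cost, "cost")
  if (cost <= 0)
    stop("weighted cost must be > 0 to form a cost-benefit ratio (got ",
         cost, ")", call. = FALSE)
  benefit / cost
}

#' Compare scenarios by cost-benefit ratio
#'
#' Ranks scenarios by descending CBR; ties are broken by scenario name
#' (ascending).  All components are echoed for audit.
#'
#' @param scenarios list of scenarios, each a list with elements `name`
#'   (unique character), `benefit` (a [benefit_components()]) and `cost`
#'   (a [cost_components()]).
#' @return a data.frame with columns `scenario`, `E`, `B`, `CBR`, `rank` and
#'   the individual weighted components, sorted by rank.
#' @export
scenario_compare <- function(scenarios) {
  if (length(scenarios) < 1L) stop("need at least one scenario", call. = FALSE)
  nms <- vapply(scenarios, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate scenario names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  rows <- lapply(scenarios, function(s) {
    E <- total_benefit(s$benefit)
    B <- total_cost(s$cost)
    data.frame(scenario = s$name, E = E, B = B, CBR = cbr(E, B),
               E_h = s$benefit$E_h, E_s = s$benefit$E_s, E_e = s$benefit$E_e,
               C_d = s$cost$C_d, C_o = s$cost$C_o, C_m = s$cost$C_m)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$CBR, out$scenario), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("scenario", "E", "B", "CBR", "rank",
          "E_h", "E_s", "E_e", "C_d", "C_o", "C_m")]
}

#' Normalise benefit or cost weights to sum to one
#'
#' Convenience helper; the model itself imposes no normalisation and this is
#' never applied implicitly.
#'
#' @param x a [benefit_components()] or [cost_components()] object.
#' @return the same object with its weights rescaled to sum to 1.
#' @export
normalize_weights <- function(x) {
  w_names <- grep("^w_", names(x), value = TRUE)
  s <- sum(unlist(x[w_names]))
  if (s <= 0) stop("weights sum to zero; cannot normalise", call. = FALSE)
  for (w in w_names) x[[w]] <- x[[w]] / s
  x
}

#' Health benefit of a trajectory (package convention)
#'
#' The economics layer never prescribes how the health benefit \eqn{E_h(T)}
#' is measured from a trajectory.  This helper adopts the package convention
#' \eqn{E_h = \mathrm{mean}(H) - H_0}: the average health gain over the
#' horizon relative to the starting state.  It is a reporting convention,
#' not part of the model.
#'
#' @param trajectory a [health_state()] trajectory.
#' @return the scalar health benefit.
#' @export
health_benefit_from_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "health_state"))
  mean(trajectory$H) - trajectory$H[1]
}
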