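#' Orifice power-law loss model
#'
#' Relates the pressure loss across a constriction to the flowrate through the
#' throat dynamic head: `dP = 0.5 * rho * K * (Q / A_C)^n`, with `Q` in mL/s
#' and `A_C` in mm^2 (their ratio is a velocity in m/s, so no further unit
#' factors appear).
#'
#' @param K dimensionless loss coefficient, `K >= 0`.
#' @param n exponent (2 for a simple orifice plate).
#' @param A_C minimum (constriction) area, mm^2.
#' @param rho fluid density, kg/m^3.
#' @return an object of class `power_law_model`.
#' @export
power_law_model <- function(K, n = 2, A_C, rho = 1.2) {
  if (K < 0) .stopf("invalid-input: K must be >= 0")
  if (A_C <= 0 || rho <= 0) .stopf("invalid-input: A_C and rho must be positive")
  structure(list(K = K, n = n, A_C = A_C, rho = rho),
            class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("<power law: dP = 0.5 * %.3g * %.4g * (Q / %.3g mm^2)^%.3g  [K*rho = %.4g]>\n",
              x$rho, x$K, x$A_C, x$n, x$K * x$rho))
  invisible(x)
}

#' Reference orifice loss coefficient from idealised stenosed-airway modelling
#'
#' The engineering-correlation value `K = 1.2` proposed as a reasonable fit
#' across a range of idealised tracheal stenosis severities (Brouns et al.,
#' Ann Biomed Eng 2007), used as the literature benchmark for predictions.
#' @export
K_REFERENCE_ORIFICE <- 1.2

#' Predict the pressure loss of a power-law model
#'
#' @param model a [power_law_model()].
#' @param Q flowrate(s), mL/s, `>= 0`.
#' @return pressure loss in Pa.
#' @export
predict_dp <- function(model, Q) {
  stopifnot(inherits(model, "power_law_model"))
  if (any(Q < 0)) .stopf("invalid-input: Q must be non-negative")
  0.5 * model$rho * model$K * (Q / model$A_C)^model$n
}

#' Fit the orifice power law to flowrate / pressure-loss pairs
#'
#' Least squares on `log(dP)`: with `n` free this is ordinary log-log
#' regression of `dP` on the throat velocity `Q/A_C`; with `n` fixed the
#' single remaining parameter is `K = exp(mean(log(dP) - log(0.5 rho
#' (Q/A_C)^n)))`, i.e. relative-error least squares to first order.  Because
#' `K` and `rho` only enter through their product, the fitted `K * rho` is
#' reported alongside `K` so an uncertain density cannot silently bias
#' comparisons.
#'
#' @param Q flowrates, mL/s (use [lmin_to_mls()] for clinical L/min tables).
#' @param dp pressure losses, Pa.
#' @param A_C minimum area, mm^2.
#' @param rho density, kg/m^3.
#' @param fixed_n if non-`NULL`, the exponent is held at this value and only
#'   `K` is fitted.
#' @return a `power_law_fit`: list with `model` ([power_law_model()]),
#'   `K_rho` (fitted `K * rho` product), `per_point_relative_error`,
#'   `max_relative_error`.
#' @export
fit_powerlaw <- function(Q, dp, A_C, rho = 1.2, fixed_n = NULL) {
  if (length(Q) != length(dp)) .stopf("invalid-input: Q and dp lengths differ")
  if (any(Q <= 0) || any(dp <= 0))
    .stopf("invalid-input: Q and dp must be positive")
  if (is.null(fixed_n) && length(Q) < 3L)
    .stopf("invalid-input: need >= 3 pairs to fit both K and n")
  if (!is.null(fixed_n) && length(Q) < 2L)
    .stopf("invalid-input: need >= 2 pairs")
  v <- Q / A_C                           # throat velocity, m/s
  if (is.null(fixed_n)) {
    fit <- stats::lm(log(dp) ~ log(v))
    n <- unname(stats::coef(fit)[2L])
    K <- 2 * exp(unname(stats::coef(fit)[1L])) / rho
  } else {
    n <- fixed_n
    K <- exp(mean(log(dp) - log(0.5 * rho * v^n)))
  }
  model <- power_law_model(K = K, n = n, A_C = A_C, rho = rho)
  pred <- predict_dp(model, Q)
  rel <- abs(pred - dp) / dp
  structure(list(model = model, K_rho = K * rho,
                 per_point_relative_error = rel,
                 max_relative_error = max(rel)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit: K = %.4g, n = %.4g (K*rho = %.4g), max rel. error %.2f%%>\n",
              x$model$K, x$model$n, x$K_rho, 100 * x$max_relative_error))
  invisible(x)
}

#' Scale a pressure loss to a different flowrate
#'
#' `dp * (Q_to / Q_from)^n` — the power-law scaling that replaces a separate
#' simulation at each flowrate of interest.
#'
#' @param dp pressure loss at `Q_from` (Pa).
#' @param Q_from,Q_to flowrates (any common unit), positive.
#' @param n exponent (2 for orifice-type losses).
#' @return scaled pressure loss (Pa).
#' @export
scale_loss <- function(dp, Q_from, Q_to, n = 2) {
  if (any(Q_from <= 0) || any(Q_to <= 0))
    .stopf("invalid-input: flowrates must be positive")
  dp * (Q_to / Q_from)^n
}

#' Scale an airway resistance to a different flowrate
#'
#' Applies `R * (Q_to / Q_from)^exponent`.  With `exponent = 2` this is the
#' convention used when quoting a resistance at a higher ventilation rate from
#' an orifice-dominated loss (note it scales `R = dP/Q` itself by the squared
#' flowrate ratio, not `dP`).
#'
#' @param R resistance (Pa.s/mL).
#' @param Q_from,Q_to flowrates (any common unit), positive.
#' @param exponent scaling exponent.
#' @return scaled resistance (Pa.s/mL).
#' @export
scale_resistance <- function(R, Q_from, Q_to, exponent = 2) {
  if (any(Q_from <= 0) || any(Q_to <= 0))
    .stopf("invalid-input: flowrates must be positive")
  R * (Q_to / Q_from)^exponent
}

#' Convert airway resistance between clinical units
#'
#' Supported units: `"Pa.s/mL"` (SI-adjacent, Pa per mL/s) and `"cmH2O.s/L"`
#' (clinical, cmH2O per L/s).  Uses 1 cmH2O = 98.0665 Pa, 1 L = 1000 mL.
#'
#' @param value resistance value(s).
#' @param from,to unit names.
#' @return converted value(s).
#' @export
convert_resistance <- function(value, from, to) {
  units <- c("Pa.s/mL", "cmH2O.s/L")
  if (!(from %in% units) || !(to %in% units))
    .stopf("invalid-unit: units must be one of %s", paste(units, collapse = ", "))
  # to Pa.s/mL first
  si <- switch(from,
               "Pa.s/mL" = value,
               "cmH2O.s/L" = value * CMH2O_PA / 1000)
  switch(to,
         "Pa.s/mL" = si,
         "cmH2O.s/L" = si * 1000 / CMH2O_PA)
}

#' Scaling exponent relating a resistance ratio to an area ratio
#'
#' Solves `R_ratio = A_ratio^p` for `p = log(R_ratio) / log(A_ratio)`; used to
#' ask how nearly a pair of constrictions follows the quadratic
#' `R ~ (1/A_C)^2` orifice behaviour.
#'
#' @param R_ratio ratio of resistances (> 0).
#' @param A_ratio ratio of areas (> 0, != 1).
#' @return the exponent `p`.
#' @export
area_ratio_exponent <- function(R_ratio, A_ratio) {
  if (R_ratio <= 0 || A_ratio <= 0)
    .stopf("invalid-input: ratios must be positive")
  if (A_ratio == 1)
    .stopf("undefined-exponent: A_ratio = 1 gives an indeterminate exponent")
  log(R_ratio) / log(A_ratio)
}
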