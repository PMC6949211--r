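#' Bundled tables from the tracheal-compression case study
#'
#' Printed summary tables of the longitudinal retrosternal-goitre case the
#' package's methods were developed against: four CT time points (T0, T4, T15
#' pre-operative; T23 post-thyroidectomy), plus truncated/derived flow models
#' (T15-S sub-glottal; T15-SG1/-SG2 with artificial inflow orifices).
#'
#' * `case_geometry_table()` — constricted length, minimum cross-sectional
#'   area, glottis area and first-tracheal-ring area per scan (mm / mm^2).
#' * `case_inflow_table()` — inflow constriction area vs. its reference area
#'   and the printed inflow constriction ratio (%), per flow model.
#' * `case_pressure_loss_table()` — pressure loss (Pa) vs. flowrate (L/min)
#'   for the most constricted geometry: row `A` inlet-to-outlet, row `B`
#'   first-ring-to-outlet, row `C` the truncated sub-glottal model over the
#'   same extent.
#' * `case_tables()` — all three in one list.
#'
#' @return a data.frame (or list of data.frames for `case_tables()`).
#' @name case_tables
NULL

#' @rdname case_tables
#' @export
case_geometry_table <- function() {
  data.frame(
    scan = c("T0", "T4", "T15", "T23"),
    constriction_length_mm = c(17.0, 32.0, 32.7, 0),
    A_min_mm2 = c(70.3, 35.2, 20.5, 80.8),
    glottis_area_mm2 = c(NA, NA, 66.9, 80.8),
    first_ring_area_mm2 = c(NA, 148, 117, 146))
}

#' @rdname case_tables
#' @export
case_inflow_table <- function() {
  data.frame(
    geometry = c("T15", "T15-S", "T15-SG1", "T15-SG2"),
    inflow_area_mm2 = c(66.9, NA, 68.3, 38.2),
    reference_area_mm2 = c(117, NA, 121, 121),
    printed_ratio_pct = c(43, 0, 44, 68))
}

#' @rdname case_tables
#' @export
case_pressure_loss_table <- function() {
  data.frame(
    row = rep(c("A", "B", "C"), each = 4L),
    extent = rep(c("inlet to outlet", "first ring to outlet",
                   "truncated, first ring to outlet"), each = 4L),
    flow_lmin = rep(c(23.5, 30, 40, 50), 3L),
    dp_Pa = c(276.8, 446.5, 774.5, 1223.9,
              206.8, 331.9, 582.3, 911.3,
              223.6, 357.6, 616.3, 950.9))
}

#' @rdname case_tables
#' @export
case_tables <- function() {
  list(geometry = case_geometry_table(),
       inflow = case_inflow_table(),
       pressure_loss = case_pressure_loss_table())
}

#' Recompute the case-study's printed derived quantities
#'
#' Every derived number quoted in the case study that can be reproduced from
#' its printed tables is recomputed with the package's own operations and
#' compared against the printed value at a stated tolerance: constriction and
#' inflow-constriction ratios, the squared minimum-area ratio, quadratic
#' flowrate scaling of the whole-airway losses, resistance scaling and unit
#' conversion, the fixed-exponent loss-coefficient fit, and the literature
#' `K = 1.2` prediction.
#'
#' The `K = 1.2` prediction is density-sensitive: the study does not state its
#' air density, and the printed "about 280 Pa" implies a rho near 1.27 kg/m^3
#' where this package defaults to 1.2 (giving about 263 Pa); its tolerance is
#' widened accordingly.  The quoted resistance-ratio exponent (about 1.9) is
#' not reproducible from the printed numbers (`log(2.4)/log(35.2/20.5)` is
#' 1.62) and is reported informationally without a pass/fail.
#'
#' @param tables list as returned by [case_tables()] (replaceable for
#'   negative-control testing).
#' @param rho air density used for the fits/predictions (kg/m^3).
#' @return data.frame with columns `check`, `computed`, `reference`, `tol`,
#'   `type` (`"abs"`/`"rel"`), `pass` (NA for informational rows), carrying
#'   one row per printed value.
#' @export
verify_case_tables <- function(tables = case_tables(), rho = 1.2) {
  g <- tables$geometry
  inf <- tables$inflow
  pl <- tables$pressure_loss
  gv <- function(scan, col) g[[col]][match(scan, g$scan)]
  dp_at <- function(row, q) pl$dp_Pa[pl$row == row & pl$flow_lmin == q]

  ratio_pct <- function(a_min, a_ref) 100 * (a_ref - a_min) / a_ref

  rows <- list()
  add <- function(check, computed, reference, tol, type, informational = FALSE) {
    err <- if (type == "abs") abs(computed - reference)
           else abs(computed - reference) / abs(reference)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, computed = computed, reference = reference,
      tol = tol, type = type,
      pass = if (informational) NA else err <= tol)
  }

  add("constriction_ratio_T15_pct",
      ratio_pct(gv("T15", "A_min_mm2"), gv("T15", "first_ring_area_mm2")),
      82.5, 0.1, "abs")
  add("constriction_ratio_T4_pct",
      ratio_pct(gv("T4", "A_min_mm2"), gv("T4", "first_ring_area_mm2")),
      76, 0.5, "abs")
  add("min_area_ratio_squared",
      (gv("T4", "A_min_mm2") / gv("T15", "A_min_mm2"))^2,
      2.9, 0.05, "abs")
  for (geom in c("T15", "T15-SG1", "T15-SG2")) {
    i <- match(geom, inf$geometry)
    add(sprintf("inflow_constriction_ratio_%s_pct", gsub("-", "", geom)),
        ratio_pct(inf$inflow_area_mm2[i], inf$reference_area_mm2[i]),
        inf$printed_ratio_pct[i], 0.6, "abs")
  }

  Q0 <- 23.5
  R0 <- dp_at("A", Q0) / lmin_to_mls(Q0)             # Pa.s/mL at 23.5 L/min
  add("resistance_30lmin_Pa_s_per_mL",
      scale_resistance(R0, Q_from = Q0, Q_to = 30, exponent = 2),
      1.16, 0.02, "abs")
  add("resistance_30lmin_cmH2O_s_per_L",
      convert_resistance(1.16, "Pa.s/mL", "cmH2O.s/L"),
      11.8, 0.05, "abs")

  for (q in c(30, 40, 50)) {
    tol <- c("30" = 0.015, "40" = 0.04, "50" = 0.03)[[as.character(q)]]
    add(sprintf("rowA_scaled_%glmin_Pa", q),
        scale_loss(dp_at("A", Q0), Q_from = Q0, Q_to = q, n = 2),
        dp_at("A", q), tol, "rel")
  }

  b <- pl[pl$row == "B", ]
  A_C <- gv("T15", "A_min_mm2")
  fit <- fit_powerlaw(lmin_to_mls(b$flow_lmin), b$dp_Pa, A_C = A_C,
                      rho = rho, fixed_n = 2)
  add("K_fit_rowB_n2", fit$model$K, 0.95, 0.03, "rel")

  add("dp_K1.2_23.5lmin_Pa",
      predict_dp(power_law_model(K = K_REFERENCE_ORIFICE, n = 2,
                                 A_C = A_C, rho = rho), Q = 392),
      280, 0.07, "rel")

  add("resistance_ratio_exponent",
      area_ratio_exponent(2.4, gv("T4", "A_min_mm2") / gv("T15", "A_min_mm2")),
      1.9, NA_real_, "abs", informational = TRUE)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
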