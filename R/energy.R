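#' Mean energy flux through a plane
#'
#' The energy flux at a station is the surface integral of normal velocity
#' times total pressure, `E_F = integral (u . n)(P_s + 0.5 rho |u|^2) dS`, in
#' watts.  Two estimators are provided:
#'
#' * `"paper_approx"` — integrate the product of the *time-averaged* total
#'   pressure and normal velocity (the standard CFD post-processing
#'   approximation);
#' * `"full_average"` — time-average the per-snapshot integral, which retains
#'   the turbulent transport contribution.
#'
#' The two agree exactly on steady fields; their difference on fluctuating
#' fields is the neglected turbulent transport term (see
#' [cumulative_loss()], which reports both).
#'
#' @param x a [plane_series()] (either mode) or a `mean_plane_field`
#'   (`"paper_approx"` only).
#' @param rho fluid density (kg/m^3).
#' @param mode estimator, see above.
#' @param discard_before start-up window excluded from averaging (s).
#' @return energy flux in W.
#' @export
energy_flux <- function(x, rho = 1.2,
                        mode = c("paper_approx", "full_average"),
                        discard_before = 0) {
  mode <- match.arg(mode)
  if (rho <= 0) .stopf("invalid-input: rho must be positive")
  if (mode == "paper_approx") {
    fld <- .as_mean_field(x, discard_before)
    un <- as.vector(fld$mean_u %*% fld$normal)
    ptot <- fld$mean_p + 0.5 * rho * rowSums(fld$mean_u^2)
    # weights mm^2 * m/s * Pa -> 1e-6 W
    return(sum(fld$weights * un * ptot) * 1e-6)
  }
  if (!inherits(x, "plane_series"))
    .stopf("invalid-input: full_average mode needs a plane_series")
  keep <- which(x$times >= discard_before)
  if (length(keep) == 0L) .stopf("empty-window: no snapshots retained")
  ef <- vapply(keep, function(t) {
    un <- as.vector(x$u[, , t] %*% x$normal)
    ptot <- x$p[, t] + 0.5 * rho * rowSums(x$u[, , t]^2)
    sum(x$weights * un * ptot)
  }, numeric(1))
  mean(ef) * 1e-6
}

#' Station-wise energy flux and cumulative energy loss
#'
#' Computes the mean energy flux at every station of a plane dataset and the
#' cumulative loss `E_F(inlet) - E_F(x)`, whose local slope is the mean local
#' dissipation rate.  The inlet is the first (most upstream) station of the
#' provided set.  Flowrate consistency across stations is checked first (mass
#' conservation within `q_tol`), since energy differences are meaningless
#' across planes carrying different flows.
#'
#' Both estimators of [energy_flux()] are tabulated; `cum_loss` uses the one
#' named by `mode`, and `turb_transport` reports their difference rather than
#' hiding it.
#'
#' @param dataset a `plane_dataset` (list of [plane_series()]).
#' @param rho fluid density (kg/m^3).
#' @param mode estimator used for the cumulative loss.
#' @param discard_before start-up window excluded from averaging (s).
#' @param q_tol allowed relative spread of station flowrates (default 1%).
#' @return an `energy_flux_profile`: data.frame with columns `x` (mm),
#'   `E_F` (W, chosen mode), `cum_loss` (W), `E_F_approx`, `E_F_full`,
#'   `turb_transport` (W); attributes `rho`, `mode`, `Q` (mean mL/s).
#' @export
cumulative_loss <- function(dataset, rho = 1.2,
                            mode = c("paper_approx", "full_average"),
                            discard_before = 0, q_tol = 0.01) {
  mode <- match.arg(mode)
  if (length(dataset) < 2L) .stopf("invalid-input: need >= 2 stations")
  fields <- lapply(dataset, .as_mean_field, discard_before = discard_before)
  x <- vapply(fields, function(f) f$station, numeric(1))
  ord <- order(x)
  fields <- fields[ord]
  dataset <- dataset[ord]
  x <- x[ord]
  Q <- vapply(fields, plane_flowrate, numeric(1))
  Qm <- mean(Q)
  if (max(abs(Q - Qm)) > q_tol * abs(Qm))
    .stopf("conservation: station flowrates differ by %.2f%% (> %.2f%% allowed)",
           100 * max(abs(Q - Qm)) / abs(Qm), 100 * q_tol)
  ef_a <- vapply(fields, energy_flux, numeric(1), rho = rho, mode = "paper_approx")
  ef_f <- vapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    if (inherits(s, "plane_series"))
      energy_flux(s, rho = rho, mode = "full_average",
                  discard_before = discard_before)
    else ef_a[i]
  }, numeric(1))
  ef <- if (mode == "paper_approx") ef_a else ef_f
  out <- data.frame(x = x, E_F = ef, cum_loss = ef[1L] - ef,
                    E_F_approx = ef_a, E_F_full = ef_f,
                    turb_transport = ef_f - ef_a)
  structure(out, class = c("energy_flux_profile", "data.frame"),
            rho = rho, mode = mode, Q = Qm)
}

#' Station-wise airway resistance profile
#'
#' `R(x) = (<P_tot>_inlet - <P_tot>_x) / Q`, with `<.>` the area-weighted mean
#' over the plane of the time-mean total pressure (static convention also
#' available).  Units Pa.s/mL when `Q` is in mL/s.  `R(inlet) = 0` by
#' construction; where the lumen expands downstream of a constriction the
#' profile can overshoot, reflecting pressure averaging across a larger area.
#'
#' @param dataset a `plane_dataset`.
#' @param Q flowrate used in the denominator (mL/s); default the measured mean
#'   station flowrate.
#' @param rho fluid density (kg/m^3), used for the dynamic-pressure term.
#' @param pressure `"total"` (default; static plus dynamic head, the
#'   convention under which `R` matches the overall `dP/Q`) or `"static"`.
#' @param discard_before start-up window excluded from averaging (s).
#' @return a `resistance_profile`: data.frame with columns `x` (mm), `R`
#'   (Pa.s/mL), `P_mean` (Pa); attributes `Q`, `pressure_convention`.
#' @export
resistance_profile <- function(dataset, Q = NULL, rho = 1.2,
                               pressure = c("total", "static"),
                               discard_before = 0) {
  pressure <- match.arg(pressure)
  fields <- lapply(dataset, .as_mean_field, discard_before = discard_before)
  x <- vapply(fields, function(f) f$station, numeric(1))
  ord <- order(x)
  fields <- fields[ord]
  x <- x[ord]
  if (is.null(Q))
    Q <- mean(vapply(fields, plane_flowrate, numeric(1)))
  if (Q <= 0) .stopf("invalid-input: Q must be positive")
  pmean <- vapply(fields, function(f) {
    p <- f$mean_p
    if (pressure == "total") p <- p + 0.5 * rho * rowSums(f$mean_u^2)
    sum(f$weights * p) / sum(f$weights)
  }, numeric(1))
  out <- data.frame(x = x, R = (pmean[1L] - pmean) / Q, P_mean = pmean)
  structure(out, class = c("resistance_profile", "data.frame"),
            Q = Q, pressure_convention = pressure)
}

#' Write energy / resistance profiles as CSV
#'
#' Schemas: `x_mm,E_F_W,cum_loss_W` and `x_mm,R_Pa_per_mLs`.
#'
#' @param profile profile object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @name profile_io
NULL

#' @rdname profile_io
#' @export
write_energy_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(x_mm = profile$x, E_F_W = profile$E_F,
                              cum_loss_W = profile$cum_loss),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @export
write_resistance_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(x_mm = profile$x, R_Pa_per_mLs = profile$R),
                   path, row.names = FALSE)
  invisible(path)
}
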