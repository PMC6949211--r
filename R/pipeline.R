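#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: either file inputs (an
#' STL lumen surface plus a centerline CSV) or a synthetic airway spec, the
#' flow conditions, and the analysis conventions.  All physical constants are
#' explicit here; nothing is hard-coded downstream.
#'
#' @param shape an [airway_shape_spec()] for synthetic runs (default: the
#'   case-study-like stenosed trachea), or `NULL` when file inputs are given.
#' @param mesh_path,centerline_path optional STL / centerline-CSV inputs used
#'   instead of the synthetic shape.
#' @param rho,mu air density (kg/m^3) and viscosity (Pa s).
#' @param threshold constriction threshold (fraction, in (0,1)).
#' @param flowrates_lmin flowrates analysed (L/min).
#' @param fixed_exponent exponent held fixed in the power-law fit.
#' @param K_true,n_true injected orifice loss of the synthetic flow.
#' @param fluctuation_rms,n_snapshots,dt synthetic fluctuation level (fraction
#'   of bulk), snapshot count and spacing (s).
#' @param discard_before start-up window discarded before averaging (s).
#' @param plane_spacing spacing of the energy-accounting planes (mm).
#' @param seed master seed; every random stage derives from it.
#' @param out_dir output directory for tables and figures.
#' @param make_figures write advisory figures (the CSV tables are the tested
#'   surface).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(shape = airway_shape_spec(),
                            mesh_path = NULL, centerline_path = NULL,
                            rho = 1.2, mu = 1.8e-5,
                            threshold = 0.35,
                            flowrates_lmin = c(23.5, 30, 40, 50),
                            fixed_exponent = 2,
                            K_true = 1.2, n_true = 2,
                            fluctuation_rms = 0.05,
                            n_snapshots = 24L, dt = 5e-4,
                            discard_before = 0,
                            plane_spacing = 4,
                            seed = 1L,
                            out_dir = tempfile("airwayflux_run_"),
                            make_figures = TRUE) {
  if (threshold <= 0 || threshold >= 1)
    .stopf("invalid-input: threshold must be in (0, 1)")
  if (rho <= 0 || mu <= 0) .stopf("invalid-input: rho and mu must be positive")
  structure(list(shape = shape, mesh_path = mesh_path,
                 centerline_path = centerline_path, rho = rho, mu = mu,
                 threshold = threshold, flowrates_lmin = flowrates_lmin,
                 fixed_exponent = fixed_exponent, K_true = K_true,
                 n_true = n_true, fluctuation_rms = fluctuation_rms,
                 n_snapshots = as.integer(n_snapshots), dt = dt,
                 discard_before = discard_before,
                 plane_spacing = plane_spacing, seed = as.integer(seed),
                 out_dir = out_dir, make_figures = make_figures),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes geometry, sampling, energy accounting and loss-model fitting in
#' order and writes the report tables (CSV) and advisory figures:
#'
#' 1. build (or read) the lumen surface and centerline; slice the mesh along
#'    the centerline into a carina-aligned area profile;
#' 2. constriction metrics at the configured threshold, reference area at the
#'    first imaged (first-ring) station;
#' 3. for each flowrate, generate the plane-sampled flow field with the
#'    injected orifice loss on the *measured* area profile, then recover
#'    energy-flux / cumulative-loss and resistance profiles;
#' 4. fit the orifice power law to the recovered (Q, dP) pairs, with the
#'    exponent both fixed and free.
#'
#' Deterministic given the seed: the per-flowrate flow seeds are derived from
#' `config$seed`, and rerunning with the same config reproduces the report
#' files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: list with `profile`, `minima`, `metrics`,
#'   `energy`, `resistance`, `pairs` (Q vs recovered dP), `fit_fixed`,
#'   `fit_free`, `files` (paths written), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- geometry ---------------------------------------------------------------
  if (!is.null(config$mesh_path)) {
    if (!file.exists(config$mesh_path))
      .stopf("missing input: mesh file %s", config$mesh_path)
    if (is.null(config$centerline_path) || !file.exists(config$centerline_path))
      .stopf("missing input: centerline file %s", config$centerline_path %||% "<unset>")
    mesh <- read_stl(config$mesh_path)
    cl <- resample_centerline(read_centerline_csv(config$centerline_path))
    imaged <- range(cl$arclength)
  } else {
    synth <- make_airway_surface(config$shape)
    mesh <- synth$mesh
    cl <- synth$centerline
    imaged <- synth$imaged_range
  }
  carina_offset <- imaged[2L]             # inferior end of the imaged region
  profile <- area_profile(mesh, cl, carina_offset = carina_offset)
  ref_station <- imaged[1L] - carina_offset  # first-ring (most superior) plane
  metrics <- constriction_metrics(profile, ref_station = ref_station,
                                  threshold = config$threshold)
  minima <- local_minima(profile, k = 3L)

  # -- flow sampling + energy accounting, per flowrate ------------------------
  # plane stations: regular spacing, plus the measured throat so the injected
  # and fitted loss see the same minimum area; regular stations within half a
  # spacing of the throat are dropped so the minimum stays unique even where
  # the measured profile is locally flat
  grid <- seq(min(profile$x), max(profile$x), by = config$plane_spacing)
  grid <- grid[abs(grid - metrics$x_min) > config$plane_spacing / 2]
  stations <- sort(c(grid, metrics$x_min))
  prof_at_planes <- new_area_profile(
    stations, stats::approx(profile$x, profile$A, xout = stations)$y)
  flows_mls <- lmin_to_mls(config$flowrates_lmin)
  runs <- lapply(seq_along(flows_mls), function(i) {
    fspec <- analytic_flow_spec(
      profile_kind = "plug", Q = flows_mls[i], rho = config$rho,
      mu = config$mu, K_true = config$K_true, n_true = config$n_true,
      fluctuation_rms = config$fluctuation_rms,
      n_snapshots = config$n_snapshots, dt = config$dt,
      seed = config$seed + i)
    fld <- make_orifice_pressure_field(fspec, prof_at_planes)
    en <- cumulative_loss(fld$dataset, rho = config$rho,
                          discard_before = config$discard_before)
    rs <- resistance_profile(fld$dataset, Q = flows_mls[i], rho = config$rho,
                             discard_before = config$discard_before)
    dp <- en$cum_loss[nrow(en)] / (flows_mls[i] * 1e-6)  # W / (m^3/s) = Pa
    list(energy = en, resistance = rs, dp = dp, dp_true = fld$dp_true)
  })
  pairs <- data.frame(Q_lmin = config$flowrates_lmin,
                      Q_mls = flows_mls,
                      dp_Pa = vapply(runs, `[[`, numeric(1), "dp"),
                      dp_true_Pa = vapply(runs, `[[`, numeric(1), "dp_true"))
  energy <- runs[[1L]]$energy
  resistance <- runs[[1L]]$resistance

  # -- loss-model fits --------------------------------------------------------
  fit_fixed <- fit_powerlaw(pairs$Q_mls, pairs$dp_Pa, A_C = metrics$A_min,
                            rho = config$rho, fixed_n = config$fixed_exponent)
  fit_free <- fit_powerlaw(pairs$Q_mls, pairs$dp_Pa, A_C = metrics$A_min,
                           rho = config$rho)

  # -- report files -----------------------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  files <- c(profile = out("area_profile.csv"),
             minima = out("area_minima.csv"),
             metrics = out("constriction_metrics.csv"),
             energy = out("energy_profile.csv"),
             resistance = out("resistance_profile.csv"),
             pairs = out("flow_pressure_pairs.csv"),
             fit = out("powerlaw_fit.csv"),
             config = out("config.txt"))
  write_area_profile_csv(profile, files["profile"])
  utils::write.csv(data.frame(x_mm = minima$x, area_mm2 = minima$A),
                   files["minima"], row.names = FALSE)
  utils::write.csv(data.frame(
    A_ref_mm2 = metrics$A_ref, A_min_mm2 = metrics$A_min,
    x_min_mm = metrics$x_min, ratio_pct = 100 * metrics$ratio,
    length_mm = metrics$length, threshold = metrics$threshold,
    widened = metrics$widened), files["metrics"], row.names = FALSE)
  write_energy_profile_csv(energy, files["energy"])
  write_resistance_profile_csv(resistance, files["resistance"])
  utils::write.csv(pairs, files["pairs"], row.names = FALSE)
  utils::write.csv(data.frame(
    parameter = c("K_fixed_n", "n_fixed", "K_free", "n_free", "K_rho_fixed_n",
                  "max_rel_error_fixed_n"),
    value = c(fit_fixed$model$K, fit_fixed$model$n, fit_free$model$K,
              fit_free$model$n, fit_fixed$K_rho,
              fit_fixed$max_relative_error)),
    files["fit"], row.names = FALSE)

  cfg_lines <- c(
    sprintf("airwayflux %s", as.character(utils::packageVersion("airwayflux"))),
    sprintf("seed: %d", config$seed),
    sprintf("rho_kg_m3: %g  mu_Pa_s: %g", config$rho, config$mu),
    sprintf("threshold: %g", config$threshold),
    sprintf("pressure_convention: %s", attr(resistance, "pressure_convention")),
    sprintf("TI_convention: area-weighted RMS |u'| over reference bulk velocity"),
    sprintf("discard_before_s: %g", config$discard_before),
    sprintf("flowrates_lmin: %s", paste(config$flowrates_lmin, collapse = ", ")),
    sprintf("fixed_exponent: %g", config$fixed_exponent),
    sprintf("K_true: %g  n_true: %g  fluctuation_rms: %g  n_snapshots: %d",
            config$K_true, config$n_true, config$fluctuation_rms,
            config$n_snapshots))
  writeLines(cfg_lines, files["config"])
  cfg_hash <- unname(tools::md5sum(files["config"]))

  if (isTRUE(config$make_figures)) {
    .fig(out("fig_area_profile.png"),
         function() plot_area_profile(profile, minima))
    .fig(out("fig_loss_profiles.png"),
         function() plot_loss_profiles(energy, resistance))
    .fig(out("fig_powerlaw_scaling.png"),
         function() plot_powerlaw_scaling(pairs, fit_fixed))
  }

  structure(list(profile = profile, minima = minima, metrics = metrics,
                 energy = energy, resistance = resistance, pairs = pairs,
                 fit_fixed = fit_fixed, fit_free = fit_free, files = files,
                 provenance = list(config_hash = cfg_hash, seed = config$seed,
                                   version = as.character(utils::packageVersion("airwayflux")))),
            class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fig <- function(path, draw) {
  grDevices::png(path, width = 900, height = 600, res = 110)
  on.exit(grDevices::dev.off())
  draw()
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  constriction: ratio %.1f%%, length %.1f mm, A_min %.1f mm^2 at x = %.1f mm\n",
              100 * x$metrics$ratio, x$metrics$length, x$metrics$A_min,
              x$metrics$x_min))
  cat(sprintf("  overall dP at %.1f L/min: %.1f Pa  (R = %.3f Pa s/mL)\n",
              x$pairs$Q_lmin[1L], x$pairs$dp_Pa[1L],
              x$pairs$dp_Pa[1L] / x$pairs$Q_mls[1L]))
  cat(sprintf("  power law: K = %.3f (n fixed at %g), K = %.3f with n = %.3f free\n",
              x$fit_fixed$model$K, x$fit_fixed$model$n,
              x$fit_free$model$K, x$fit_free$model$n))
  cat(sprintf("  tables in %s\n", dirname(x$files[["profile"]])))
  invisible(x)
}

#' Diagnostic figures
#'
#' Base-graphics renderings of the report tables: the carina-aligned area
#' profile with its minima marked, the paired cumulative-loss / resistance
#' profiles, and computed pressure losses against the quadratic scaling from
#' the lowest flowrate.  Figures are advisory; the CSV tables are the tested
#' surface.
#'
#' @param profile,minima,energy,resistance,pairs,fit report components.
#' @return invisibly, `NULL`.
#' @name report_figures
NULL

#' @rdname report_figures
#' @export
plot_area_profile <- function(profile, minima = NULL) {
  graphics::plot(profile$x, profile$A, type = "l", lwd = 2,
                 xlab = "distance from carina x (mm)",
                 ylab = expression("cross-sectional area (mm"^2 * ")"),
                 main = "Lumen area profile")
  if (!is.null(minima) && nrow(minima))
    graphics::points(minima$x, minima$A, pch = 15, cex = 1.4)
  invisible(NULL)
}

#' @rdname report_figures
#' @export
plot_loss_profiles <- function(energy, resistance) {
  old <- graphics::par(mar = c(5, 4, 4, 4.5))
  on.exit(graphics::par(old))
  graphics::plot(resistance$x, resistance$R, type = "l", lwd = 2,
                 xlab = "distance from carina x (mm)",
                 ylab = "resistance (Pa s/mL)",
                 main = "Resistance and cumulative energy loss")
  graphics::par(new = TRUE)
  graphics::plot(energy$x, energy$cum_loss, type = "l", lty = 2, lwd = 2,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("cumulative loss (W)", side = 4, line = 3)
  graphics::legend("topleft", legend = c("resistance", "cumulative loss"),
                   lty = c(1, 2), lwd = 2, bty = "n")
  invisible(NULL)
}

#' @rdname report_figures
#' @export
plot_powerlaw_scaling <- function(pairs, fit) {
  q <- seq(min(pairs$Q_mls), max(pairs$Q_mls), length.out = 100)
  scaled <- scale_loss(pairs$dp_Pa[1L], pairs$Q_mls[1L], q,
                       n = fit$model$n)
  graphics::plot(pairs$Q_lmin, pairs$dp_Pa, pch = 16, cex = 1.3,
                 xlab = "flowrate (L/min)", ylab = "pressure loss (Pa)",
                 main = "Quadratic flowrate scaling of the loss")
  graphics::lines(mls_to_lmin(q), scaled, lwd = 2)
  graphics::lines(mls_to_lmin(q), predict_dp(fit$model, q), lty = 2, lwd = 2)
  graphics::legend("topleft",
                   legend = c("computed", "scaled from lowest flowrate",
                              "fitted power law"),
                   pch = c(16, NA, NA), lty = c(NA, 1, 2), lwd = 2, bty = "n")
  invisible(NULL)
}
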