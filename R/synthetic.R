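#' Specification of a parametric stenosed airway surface
#'
#' The tube axis runs along z.  The lumen is an ellipse whose area is modulated
#' by a Gaussian constriction: `A(x) = pi * a(x) * b(x) = A0 * (1 - c *
#' exp(-(x - x0)^2 / (2 sigma^2)))`, with `A0 = pi * base_radius^2`.  The
#' Gaussian factor applies to the *area* (the radii are scaled by its square
#' root), so `constriction_depth` is exactly the fractional area reduction at
#' the throat: `c = 0.825` reproduces an 82.5% constriction ratio.
#'
#' Defaults emulate the severely compressed trachea of the case study: a
#' 100 mm trachea with first-ring area 117 mm^2 (`base_radius = 6.103`),
#' an 82.5% deep constriction, and `sigma = 12.49 mm` so that the 35%-reduction
#' constricted length is 32.7 mm.  Straight extrusions of 35 mm (about three
#' hydraulic diameters) are added at both ends, as is common practice to move
#' inflow/outflow boundaries away from the region of interest.
#'
#' @param length imaged tube length (mm).
#' @param base_radius unconstricted effective radius (mm); `A0 = pi r^2`.
#' @param ellipticity minor/major axis ratio of the lumen (1 = circular);
#'   area is preserved for any value.
#' @param constriction_depth fractional area reduction `c` at the throat,
#'   in `[0, 1)`.
#' @param constriction_center throat station `x0` (mm along the imaged tube).
#' @param constriction_width Gaussian width `sigma` (mm).
#' @param extrusion_length straight extension added at each end (mm).
#' @param mesh_edge target mesh edge length (mm); controls both azimuthal and
#'   axial resolution.
#' @param seed integer seed stored with the spec (mesh construction itself is
#'   deterministic; the seed keys any flow sampling built on the surface).
#' @return an object of class `airway_shape_spec`.
#' @export
airway_shape_spec <- function(length = 100,
                              base_radius = 6.103,
                              ellipticity = 1,
                              constriction_depth = 0.825,
                              constriction_center = length / 2,
                              constriction_width = 12.49,
                              extrusion_length = 35,
                              mesh_edge = 0.6,
                              seed = 1L) {
  if (constriction_depth < 0 || constriction_depth >= 1)
    .stopf("invalid-spec: constriction_depth must be in [0, 1)")
  if (constriction_width <= 0) .stopf("invalid-spec: constriction_width > 0")
  if (mesh_edge <= 0) .stopf("invalid-spec: mesh_edge > 0")
  if (ellipticity <= 0 || ellipticity > 1)
    .stopf("invalid-spec: ellipticity must be in (0, 1]")
  structure(list(length = length, base_radius = base_radius,
                 ellipticity = ellipticity,
                 constriction_depth = constriction_depth,
                 constriction_center = constriction_center,
                 constriction_width = constriction_width,
                 extrusion_length = extrusion_length,
                 mesh_edge = mesh_edge, seed = as.integer(seed)),
            class = "airway_shape_spec")
}

# Area modulation factor (applies to area; clamped outside the imaged tube so
# the extrusions are straight).
.area_factor <- function(spec, s) {
  z <- pmin(pmax(s, 0), spec$length)
  1 - spec$constriction_depth *
    exp(-(z - spec$constriction_center)^2 / (2 * spec$constriction_width^2))
}

#' Analytic lumen area of a shape spec
#'
#' @param spec an [airway_shape_spec()].
#' @param s station along the imaged tube (mm; 0 at the superior end).
#' @return areas in mm^2.
#' @export
airway_area <- function(spec, s) {
  pi * spec$base_radius^2 * .area_factor(spec, s)
}

#' Generate a stenosed airway surface mesh with centerline and analytic profile
#'
#' Builds a watertight triangulated tube (rings of vertices joined by quads
#' split into triangles, capped with vertex fans), a straight centerline
#' resampled at 1 mm, and the analytic area profile sampled at the centerline
#' stations.  Station coordinates are raw arclength measured from the start of
#' the extruded inlet.
#'
#' @param spec an [airway_shape_spec()].
#' @return list with elements `mesh` ([tri_mesh()]), `centerline`
#'   ([centerline()]), `profile` (analytic `area_profile` at the centerline
#'   stations), `area_fun` (function of raw arclength), and `imaged_range`
#'   (raw-arclength interval of the imaged tube, excluding extrusions).
#' @export
make_airway_surface <- function(spec) {
  stopifnot(inherits(spec, "airway_shape_spec"))
  ext <- spec$extrusion_length
  z0 <- -ext
  z1 <- spec$length + ext
  ntheta <- max(24L, as.integer(round(2 * pi * spec$base_radius / spec$mesh_edge)))
  nz <- max(2L, as.integer(round((z1 - z0) / spec$mesh_edge)) + 1L)
  z <- seq(z0, z1, length.out = nz)
  rf <- sqrt(.area_factor(spec, z))
  a <- spec$base_radius * rf / sqrt(spec$ellipticity)   # major semi-axis
  b <- spec$base_radius * rf * sqrt(spec$ellipticity)   # minor semi-axis
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  ct <- cos(th); st <- sin(th)

  verts <- matrix(0, nz * ntheta + 2L, 3L)
  for (i in seq_len(nz)) {
    idx <- (i - 1L) * ntheta + seq_len(ntheta)
    verts[idx, ] <- cbind(a[i] * ct, b[i] * st, z[i])
  }
  c_bot <- nz * ntheta + 1L
  c_top <- nz * ntheta + 2L
  verts[c_bot, ] <- c(0, 0, z0)
  verts[c_top, ] <- c(0, 0, z1)

  ring <- function(i) (i - 1L) * ntheta + seq_len(ntheta)
  nxt <- c(seq_len(ntheta)[-1L], 1L)
  faces <- vector("list", nz + 1L)
  for (i in seq_len(nz - 1L)) {
    r1 <- ring(i); r2 <- ring(i + 1L)
    faces[[i]] <- rbind(cbind(r1, r1[nxt], r2[nxt]),
                        cbind(r1, r2[nxt], r2))
  }
  r1 <- ring(1L); rn <- ring(nz)
  faces[[nz]] <- cbind(r1[nxt], r1, c_bot)          # bottom cap
  faces[[nz + 1L]] <- cbind(rn, rn[nxt], c_top)     # top cap
  mesh <- tri_mesh(verts, do.call(rbind, faces))

  # centerline inset by one mesh edge from the end caps so every slicing
  # plane intersects the tube interior
  inset <- spec$mesh_edge
  cl <- resample_centerline(rbind(c(0, 0, z0 + inset), c(0, 0, z1 - inset)),
                            spacing = 1)
  s <- cl$arclength                  # raw arclength from the (inset) inlet
  area_fun <- function(s_raw) airway_area(spec, s_raw - ext + inset)
  profile <- new_area_profile(s, area_fun(s))
  list(mesh = mesh, centerline = cl, profile = profile, area_fun = area_fun,
       imaged_range = c(ext - inset, ext - inset + spec$length))
}

#' Specification of an analytic plane-sampled flow field
#'
#' @param profile_kind velocity profile shape: `"plug"`, `"parabolic"`
#'   (Poiseuille-like) or `"orifice_jet"` (top-hat jet filling the throat
#'   area).
#' @param Q bulk flowrate (mL/s).  Default 392 mL/s, the study's quiet
#'   inhalation peak (23.5 L/min).
#' @param rho fluid density (kg/m^3); default 1.2 (room air).
#' @param mu dynamic viscosity (Pa s); default 1.8e-5 (air).
#' @param K_true,n_true loss coefficient and exponent of the injected orifice
#'   loss (used by [make_orifice_pressure_field()]).
#' @param fluctuation_rms RMS of the synthetic velocity fluctuation vector as a
#'   fraction of the local bulk velocity (white in space and time).
#' @param n_snapshots number of time snapshots.
#' @param dt snapshot spacing (s).
#' @param n_radial,n_azimuth quadrature resolution per plane.
#' @param seed RNG seed for the fluctuations.
#' @return an object of class `analytic_flow_spec`.
#' @export
analytic_flow_spec <- function(profile_kind = c("plug", "parabolic", "orifice_jet"),
                               Q = 392, rho = 1.2, mu = 1.8e-5,
                               K_true = 1.2, n_true = 2,
                               fluctuation_rms = 0, n_snapshots = 1L,
                               dt = 5e-4, n_radial = 12L, n_azimuth = 32L,
                               seed = 1L) {
  profile_kind <- match.arg(profile_kind)
  if (Q <= 0 || rho <= 0) .stopf("invalid-spec: Q and rho must be positive")
  if (fluctuation_rms < 0) .stopf("invalid-spec: fluctuation_rms >= 0")
  structure(list(profile_kind = profile_kind, Q = Q, rho = rho, mu = mu,
                 K_true = K_true, n_true = n_true,
                 fluctuation_rms = fluctuation_rms,
                 n_snapshots = as.integer(n_snapshots), dt = dt,
                 n_radial = as.integer(n_radial),
                 n_azimuth = as.integer(n_azimuth), seed = as.integer(seed)),
            class = "analytic_flow_spec")
}

#' Analytic elliptical cross-sections along the tube axis
#'
#' Builds `cross_section` objects (polygonal ellipse loops on planes normal to
#' z) from an area law, for feeding [make_plane_samples()].
#'
#' @param area area law: a function of station, or a vector of areas (mm^2)
#'   matching `stations`.
#' @param stations station coordinates (mm); also the z position of each plane.
#' @param ellipticity minor/major axis ratio.
#' @param ntheta polygon resolution of each loop.
#' @return list of `cross_section` objects.
#' @export
analytic_sections <- function(area, stations, ellipticity = 1, ntheta = 64L) {
  A <- if (is.function(area)) area(stations) else rep_len(area, length(stations))
  th <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  lapply(seq_along(stations), function(i) {
    r <- sqrt(A[i] / pi)
    a <- r / sqrt(ellipticity); b <- r * sqrt(ellipticity)
    loop <- cbind(a * cos(th), b * sin(th), stations[i])
    m <- .loop_metrics(loop, c(0, 0, 1))
    structure(list(station = stations[i], origin = c(0, 0, stations[i]),
                   normal = c(0, 0, 1), loops = list(loop), area = m$area,
                   perimeter = m$perimeter,
                   hydraulic_diameter = 4 * m$area / m$perimeter,
                   centroid = m$centroid),
              class = "cross_section")
  })
}

#' Quadrature sample points inside a cross-section
#'
#' Maps a polar grid onto the (star-shaped) section through its centroid: for
#' each azimuthal sector the boundary radius is found by ray-polygon
#' intersection, and radial nodes are placed at the root-mean-square radius of
#' equal-`f^2` annular cells, which integrates any profile of the form
#' `g(f^2)` that is linear in `f^2` exactly.  Cell areas are sum-normalised to
#' the polygon area (so the weights always add up to the section area).
#'
#' @param section a `cross_section`.
#' @param n_radial,n_azimuth grid resolution.
#' @return list with `points` (`n x 3`, mm), `weights` (mm^2, summing to the
#'   section area), `f` (radial fraction in `[0,1]` per point).
#' @export
sample_section_points <- function(section, n_radial = 12L, n_azimuth = 32L) {
  loop <- section$loops[[1L]]
  bas <- .plane_basis(section$normal)
  ref <- section$centroid
  rel <- sweep(loop, 2, ref)
  px <- as.vector(rel %*% bas$e1)
  py <- as.vector(rel %*% bas$e2)
  th <- 2 * pi * (seq_len(n_azimuth) - 0.5) / n_azimuth
  rb <- vapply(th, function(t) .ray_boundary(px, py, t), numeric(1))
  g_mid <- (2 * seq_len(n_radial) - 1) / (2 * n_radial)
  f <- sqrt(g_mid)
  pts <- matrix(0, n_radial * n_azimuth, 3L)
  w <- numeric(n_radial * n_azimuth)
  ff <- numeric(n_radial * n_azimuth)
  dth <- 2 * pi / n_azimuth
  k <- 0L
  for (j in seq_len(n_azimuth)) {
    dir3 <- cos(th[j]) * bas$e1 + sin(th[j]) * bas$e2
    for (i in seq_len(n_radial)) {
      k <- k + 1L
      pts[k, ] <- ref + f[i] * rb[j] * dir3
      w[k] <- rb[j]^2 * dth / (2 * n_radial)
      ff[k] <- f[i]
    }
  }
  w <- w * section$area / sum(w)
  list(points = pts, weights = w, f = ff)
}

# Distance from the origin to the polygon boundary along direction theta
# (polygon given in local 2D coordinates about its centroid).
.ray_boundary <- function(px, py, theta) {
  dx <- cos(theta); dy <- sin(theta)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  ex <- x2 - px; ey <- y2 - py
  den <- dx * ey - dy * ex
  ok <- abs(den) > 1e-14
  t <- (px * ey - py * ex) / den          # distance along the ray
  u <- (px * dy - py * dx) / den          # position along the segment
  hit <- ok & t > 0 & u >= -1e-12 & u <= 1 + 1e-12
  if (!any(hit)) .stopf("topology: section polygon is not star-shaped from its centroid")
  min(t[hit])
}

#' Generate a time-resolved plane-sample dataset
#'
#' For each section the named velocity-profile shape is evaluated on the
#' quadrature points and rescaled so the discrete flowrate equals `spec$Q`
#' exactly; white Gaussian fluctuations (isotropic over the three components,
#' with vector RMS equal to `fluctuation_rms` times the local bulk velocity)
#' are added independently per point and snapshot.  Static pressure is uniform
#' over each plane and constant in time, given by `pressure_fun(station)`.
#'
#' @param spec an [analytic_flow_spec()].
#' @param sections list of `cross_section` objects (e.g. from
#'   [analytic_sections()] or mesh slicing).
#' @param pressure_fun function of station returning static pressure (Pa).
#' @return a `plane_dataset`: list of [plane_series()] objects, one per
#'   section, ordered by station, with the flow spec attached as an attribute.
#' @export
make_plane_samples <- function(spec, sections, pressure_fun = function(x) 0) {
  stopifnot(inherits(spec, "analytic_flow_spec"))
  A_all <- vapply(sections, function(s) s$area, numeric(1))
  A_throat <- min(A_all)
  times <- (seq_len(spec$n_snapshots) - 1L) * spec$dt
  old_seed <- .save_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(spec$seed)
  series <- lapply(sections, function(sec) {
    sp <- sample_section_points(sec, spec$n_radial, spec$n_azimuth)
    g <- switch(spec$profile_kind,
                plug = rep(1, length(sp$f)),
                parabolic = 2 * (1 - sp$f^2),
                orifice_jet = as.numeric(sp$f <= sqrt(min(1, A_throat / sec$area))))
    u_mag <- g * spec$Q / sum(sp$weights * g)   # mm^2 * m/s == mL/s
    U_bulk <- spec$Q / sec$area
    n_pts <- length(u_mag)
    u <- array(0, c(n_pts, 3L, spec$n_snapshots))
    base <- outer(u_mag, sec$normal)            # n_pts x 3
    sd_c <- spec$fluctuation_rms * U_bulk / sqrt(3)
    for (t in seq_len(spec$n_snapshots)) {
      u[, , t] <- base
      if (sd_c > 0)
        u[, , t] <- u[, , t] + matrix(stats::rnorm(n_pts * 3L, sd = sd_c), n_pts, 3L)
    }
    p <- matrix(pressure_fun(sec$station), n_pts, spec$n_snapshots)
    plane_series(points = sp$points, weights = sp$weights, normal = sec$normal,
                 station = sec$station, area = sec$area, times = times,
                 u = u, p = p, f = sp$f)
  })
  ord <- order(vapply(series, function(s) s$station, numeric(1)))
  structure(series[ord], class = "plane_dataset", flow_spec = spec)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Impose an orifice-type loss on a duct flow and sample it on planes
#'
#' Builds a plug-flow plane dataset on circular sections following the given
#' area profile, with a static pressure law consistent with Bernoulli on the
#' area change plus an irreversible total-pressure drop of
#' `0.5 * rho * K_true * (Q / A_C)^n_true` imposed across the constriction.
#' The drop is distributed downstream of the throat over a mixing length
#' (default 5 hydraulic diameters of the throat, emulating the gradual decline
#' of energy flux where a constriction jet breaks up) using a smoothstep ramp.
#' The injected loss is returned exactly, so energy accounting can be verified
#' against ground truth.
#'
#' @param spec an [analytic_flow_spec()] (its `profile_kind` is overridden to
#'   plug flow, which makes the plane total pressure exactly uniform).
#' @param profile an `area_profile` with a unique minimum (the throat).
#' @param mixing_length mixing length (mm); default `5 *` throat hydraulic
#'   diameter.
#' @param ellipticity section ellipticity passed to [analytic_sections()].
#' @return list with `dataset` (a `plane_dataset`), `dp_true` (injected
#'   total-pressure loss, Pa), `total_pressure` and `static_pressure`
#'   (functions of station, Pa), `A_C` (mm^2), `x_throat` (mm),
#'   `mixing_length` (mm).
#' @export
make_orifice_pressure_field <- function(spec, profile, mixing_length = NULL,
                                        ellipticity = 1) {
  stopifnot(inherits(spec, "analytic_flow_spec"))
  A <- profile$A; x <- profile$x
  i_min <- which(A == min(A))
  if (length(i_min) != 1L)
    .stopf("invalid-spec: the area profile must have a unique minimum")
  A_C <- A[i_min]; x_throat <- x[i_min]
  if (is.null(mixing_length))
    mixing_length <- 5 * 2 * sqrt(A_C / pi)     # 5 x throat hydraulic diameter
  dp_true <- 0.5 * spec$rho * spec$K_true * (spec$Q / A_C)^spec$n_true

  ramp <- function(s) {
    t <- pmin(pmax((s - x_throat) / mixing_length, 0), 1)
    t^2 * (3 - 2 * t)
  }
  secs <- analytic_sections(function(s) stats::approx(x, A, xout = s, rule = 2)$y,
                            x, ellipticity = ellipticity)
  # Bernoulli on the realised (polygonal) section areas, so the injected
  # total-pressure law is recovered by the plane quadrature to rounding error.
  A_sec <- vapply(secs, function(s) s$area, numeric(1))
  area_at <- function(s) stats::approx(x, A_sec, xout = s, rule = 2)$y
  U_in <- spec$Q / A_sec[1L]
  total_pressure <- function(s) -dp_true * ramp(s)
  static_pressure <- function(s)
    total_pressure(s) + 0.5 * spec$rho * U_in^2 -
      0.5 * spec$rho * (spec$Q / area_at(s))^2

  plug_spec <- spec
  plug_spec$profile_kind <- "plug"
  dataset <- make_plane_samples(plug_spec, secs, pressure_fun = static_pressure)
  list(dataset = dataset, dp_true = dp_true, total_pressure = total_pressure,
       static_pressure = static_pressure, A_C = A_C, x_throat = x_throat,
       mixing_length = mixing_length)
}
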