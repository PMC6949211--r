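# Shared fixtures, built in code. The default stenosed airway (mesh + mesh-
# derived profile) is expensive enough to build once and reuse.

.cache <- new.env(parent = emptyenv())

default_airway <- function() {
  if (is.null(.cache$airway)) .cache$airway <- make_airway_surface(airway_shape_spec())
  .cache$airway
}

default_mesh_profile <- function() {
  if (is.null(.cache$profile)) {
    aw <- default_airway()
    .cache$profile <- area_profile(aw$mesh, aw$centerline,
                                   carina_offset = aw$imaged_range[2])
  }
  .cache$profile
}

# uniform circular tube mesh with n azimuthal facets
cylinder_mesh <- function(radius = 10, length = 40, ntheta = 64) {
  spec <- airway_shape_spec(length = length, base_radius = radius,
                            constriction_depth = 0, extrusion_length = 0,
                            mesh_edge = 2 * pi * radius / ntheta)
  make_airway_surface(spec)$mesh
}

# a plane_series built directly from an explicit velocity/pressure state
steady_plane_series <- function(u_axial, p = 0, area = 100, n_pts = 50,
                                station = 0, normal = c(0, 0, 1),
                                n_snapshots = 1, times = NULL) {
  pts <- cbind(seq_len(n_pts), 0, station)
  w <- rep(area / n_pts, n_pts)
  if (is.null(times)) times <- (seq_len(n_snapshots) - 1) * 1e-3
  nt <- length(times)
  u <- array(0, c(n_pts, 3, nt))
  for (t in seq_len(nt)) u[, 3, t] <- u_axial
  plane_series(points = pts, weights = w, normal = normal, station = station,
               area = area, times = times,
               u = u, p = matrix(p, n_pts, nt))
}

uniform_sections <- function(area = 100, stations = c(0, 50, 100),
                             ntheta = 64) {
  analytic_sections(function(x) rep(area, length(x)), stations,
                    ntheta = ntheta)
}
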