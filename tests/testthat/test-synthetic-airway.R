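test_that("an unconstricted spec yields a uniform watertight tube", {
  spec <- airway_shape_spec(length = 40, base_radius = 5,
                            constriction_depth = 0, extrusion_length = 10,
                            mesh_edge = 1)
  s <- make_airway_surface(spec)
  expect_true(is_watertight(s$mesh))
  expect_lt(diff(range(s$profile$A)), 1e-9)
  expect_equal(s$profile$A[1], pi * 25, tolerance = 1e-9)
})

test_that("generation is deterministic", {
  s1 <- make_airway_surface(airway_shape_spec(length = 30, mesh_edge = 1.5))
  s2 <- make_airway_surface(airway_shape_spec(length = 30, mesh_edge = 1.5))
  expect_identical(s1$mesh, s2$mesh)
  expect_identical(s1$profile, s2$profile)
})

test_that("invalid shape specs are rejected", {
  expect_error(airway_shape_spec(constriction_depth = 1), "invalid-spec")
  expect_error(airway_shape_spec(constriction_depth = -0.1), "invalid-spec")
  expect_error(airway_shape_spec(mesh_edge = 0), "invalid-spec")
})

test_that("the default airway reproduces the target 82.5% constriction ratio", {
  aw <- default_airway()
  pr <- default_mesh_profile()
  m <- constriction_metrics(pr, ref_station = aw$imaged_range[1] - aw$imaged_range[2])
  expect_lt(abs(100 * m$ratio - 82.5), 1)
  expect_lt(abs(m$length - 32.7), 0.5)
})

test_that("mesh-derived areas converge to the analytic law under refinement", {
  err_at <- function(edge) {
    spec <- airway_shape_spec(length = 40, constriction_center = 20,
                              constriction_width = 8, extrusion_length = 5,
                              mesh_edge = edge)
    s <- make_airway_surface(spec)
    st <- c(15, 25, 35)                  # z positions on the imaged tube
    measured <- vapply(st, function(z) {
      slice_area(s$mesh, c(0, 0, z), c(0, 0, 1))$area
    }, numeric(1))
    max(abs(measured / airway_area(spec, st) - 1))
  }
  errs <- vapply(c(1.6, 0.8, 0.4), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.002)
})

test_that("elliptical lumens preserve the analytic area", {
  spec <- airway_shape_spec(length = 30, base_radius = 6, ellipticity = 0.6,
                            constriction_depth = 0.5, constriction_center = 15,
                            extrusion_length = 5, mesh_edge = 0.5)
  s <- make_airway_surface(spec)
  # station z = 15 on the imaged tube sits at mesh z = 15; slice directly there
  sec <- slice_area(s$mesh, c(0, 0, 15), c(0, 0, 1))
  expect_equal(sec$area, airway_area(spec, 15), tolerance = 0.01)
})

test_that("plane samples follow the requested velocity profile", {
  secs <- uniform_sections(area = 100)
  U <- 392 / secs[[1]]$area               # bulk velocity on the realised area
  par <- make_plane_samples(analytic_flow_spec("parabolic", Q = 392), secs)
  s1 <- par[[1]]
  # pointwise Poiseuille law with centreline factor 2: u = 2U(1 - f^2)
  expect_equal(s1$u[, 3, 1], 2 * U * (1 - s1$f^2), tolerance = 1e-9)
  expect_lt(max(s1$u[, 3, 1]), 2 * U)
  # the sampled peak approaches 2U as the radial quadrature refines
  fine <- make_plane_samples(analytic_flow_spec("parabolic", Q = 392,
                                                n_radial = 64L), secs)
  expect_equal(max(fine[[1]]$u[, 3, 1]), 2 * U, tolerance = 0.01)
  expect_equal(plane_flowrate(s1), 392, tolerance = 1e-9)

  plug <- make_plane_samples(analytic_flow_spec("plug", Q = 392), secs)
  expect_lt(diff(range(plug[[1]]$u[, 3, 1])), 1e-12)

  expect_error(analytic_flow_spec("swirl"), "arg")
})

test_that("zero-fluctuation series are steady; prescribed RMS is recovered", {
  secs <- uniform_sections(area = 100, stations = c(0, 40))
  steady <- make_plane_samples(
    analytic_flow_spec("plug", Q = 392, fluctuation_rms = 0, n_snapshots = 5),
    secs)
  expect_identical(steady[[1]]$u[, , 1], steady[[1]]$u[, , 5])

  turb <- make_plane_samples(
    analytic_flow_spec("plug", Q = 392, fluctuation_rms = 0.05,
                       n_snapshots = 96, seed = 11), secs)
  fld <- time_average(turb[[1]])
  U <- 392 / 100
  measured <- sum(fld$weights * fld$fluctuation_rms) / sum(fld$weights) / U
  # RMS about the sample mean is biased by sqrt(1 - 1/T); compare against that,
  # with a band generous enough for the residual sampling error
  expect_equal(measured, 0.05 * sqrt(1 - 1 / 96), tolerance = 0.003)
  expect_equal(measured, 0.05, tolerance = 0.015)
})

test_that("seeded flow sampling is reproducible bit for bit", {
  secs <- uniform_sections(area = 80, stations = 0)
  sp <- analytic_flow_spec("plug", Q = 200, fluctuation_rms = 0.1,
                           n_snapshots = 4, seed = 99)
  d1 <- make_plane_samples(sp, secs)
  d2 <- make_plane_samples(sp, secs)
  expect_identical(d1[[1]]$u, d2[[1]]$u)
})

test_that("the orifice pressure field injects exactly the power-law loss", {
  prof <- new_area_profile(c(0, 25, 50, 75, 100), c(117, 60, 20.5, 60, 117))
  sp <- analytic_flow_spec("plug", Q = 392, rho = 1.2, K_true = 1.2,
                           n_true = 2)
  orf <- make_orifice_pressure_field(sp, prof)
  expect_equal(orf$dp_true, 0.5 * 1.2 * 1.2 * (392 / 20.5)^2, tolerance = 1e-12)
  expect_equal(orf$A_C, 20.5)

  # doubling Q quadruples the injected loss at n = 2
  sp2 <- analytic_flow_spec("plug", Q = 784, rho = 1.2, K_true = 1.2, n_true = 2)
  orf2 <- make_orifice_pressure_field(sp2, prof)
  expect_equal(orf2$dp_true / orf$dp_true, 4, tolerance = 1e-12)

  # K_true = 0: total pressure constant along the duct
  sp0 <- analytic_flow_spec("plug", Q = 392, K_true = 0)
  orf0 <- make_orifice_pressure_field(sp0, prof)
  expect_equal(orf0$dp_true, 0)
  xs <- seq(0, 100, 10)
  expect_lt(max(abs(orf0$total_pressure(xs))), 1e-12)

  # a non-unique minimum is rejected
  flat2 <- new_area_profile(c(0, 25, 50, 75), c(117, 20.5, 20.5, 117))
  expect_error(make_orifice_pressure_field(sp, flat2), "unique minimum")
})
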