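rho_air <- 1.2

test_that("energy flux of plug flow is Q * (P + 0.5 rho U^2)", {
  s <- steady_plane_series(u_axial = 4, p = 30, area = 100)
  Q_si <- 4 * 100 * 1e-6                        # m^3/s
  expect_equal(energy_flux(s, rho = rho_air),
               Q_si * (30 + 0.5 * rho_air * 16), tolerance = 1e-12)
})

test_that("energy flux of Poiseuille flow carries the kinetic factor 2", {
  secs <- uniform_sections(area = 100, stations = 0)
  d <- make_plane_samples(analytic_flow_spec("parabolic", Q = 392), secs,
                          pressure_fun = function(x) 25)
  U <- 392 / 100                                 # bulk velocity m/s
  Q_si <- 392e-6
  expect_equal(energy_flux(d[[1]], rho = rho_air),
               Q_si * 25 + rho_air * Q_si * U^2, tolerance = 0.005)
})

test_that("both energy-flux estimators agree exactly on steady fields", {
  s <- steady_plane_series(u_axial = seq(1, 3, length.out = 50), p = 12,
                           n_snapshots = 6)
  expect_equal(energy_flux(s, rho_air, "paper_approx"),
               energy_flux(s, rho_air, "full_average"), tolerance = 1e-14)
})

test_that("energy-flux estimators match a brute-force point/snapshot summation", {
  secs <- uniform_sections(area = 90, stations = 0, ntheta = 32)
  d <- make_plane_samples(
    analytic_flow_spec("parabolic", Q = 300, fluctuation_rms = 0.1,
                       n_snapshots = 7, seed = 13, n_radial = 6,
                       n_azimuth = 12),
    secs, pressure_fun = function(x) 40)
  s <- d[[1]]
  nt <- length(s$times); np <- nrow(s$points)
  ef_full <- 0
  for (t in seq_len(nt)) {
    acc <- 0
    for (i in seq_len(np)) {
      un <- sum(s$u[i, , t] * s$normal)
      acc <- acc + s$weights[i] * un *
        (s$p[i, t] + 0.5 * rho_air * sum(s$u[i, , t]^2))
    }
    ef_full <- ef_full + acc
  }
  ef_full <- ef_full / nt * 1e-6
  ubar <- apply(s$u, c(1, 2), mean); pbar <- rowMeans(s$p)
  ef_approx <- 0
  for (i in seq_len(np)) {
    un <- sum(ubar[i, ] * s$normal)
    ef_approx <- ef_approx + s$weights[i] * un *
      (pbar[i] + 0.5 * rho_air * sum(ubar[i, ]^2))
  }
  ef_approx <- ef_approx * 1e-6
  expect_equal(energy_flux(s, rho_air, "full_average"), ef_full,
               tolerance = 1e-12)
  expect_equal(energy_flux(s, rho_air, "paper_approx"), ef_approx,
               tolerance = 1e-12)
  # on a fluctuating field the difference is the turbulent transport term
  expect_gt(abs(ef_full - ef_approx), 0)
})

orifice_dataset <- function(Q = 392, K_true = 1.2, rms = 0.05, seed = 3,
                            n_snapshots = 24) {
  aw <- default_airway()
  st <- seq(10, 160, by = 5)
  prof <- new_area_profile(st, aw$area_fun(st))
  make_orifice_pressure_field(
    analytic_flow_spec("plug", Q = Q, rho = rho_air, K_true = K_true,
                       n_true = 2, fluctuation_rms = rms,
                       n_snapshots = n_snapshots, seed = seed), prof)
}

test_that("cumulative loss recovers the injected orifice loss within 1%", {
  orf <- orifice_dataset()
  en <- cumulative_loss(orf$dataset, rho = rho_air)
  injected_W <- 392e-6 * orf$dp_true
  expect_equal(en$cum_loss[nrow(en)], injected_W, tolerance = 0.01)
  expect_equal(en$cum_loss[1], 0)
})

test_that("a lossless Bernoulli dataset accumulates no loss", {
  orf <- orifice_dataset(K_true = 0, rms = 0, n_snapshots = 1)
  en <- cumulative_loss(orf$dataset, rho = rho_air)
  # scale: compare against the throat dynamic-head flux
  scale_W <- 392e-6 * 0.5 * rho_air * (392 / orf$A_C)^2
  expect_lt(max(abs(en$cum_loss)), 1e-9 * scale_W)
})

test_that("cumulative loss is non-decreasing when the injected dissipation is non-negative", {
  orf <- orifice_dataset(rms = 0, n_snapshots = 1)
  en <- cumulative_loss(orf$dataset, rho = rho_air)
  expect_true(all(diff(en$cum_loss) > -1e-12))
  expect_identical(attr(en, "mode"), "paper_approx")
})

test_that("a linear static-pressure drop gives a loss linear in x", {
  secs <- analytic_sections(function(x) rep(pi * 4, length(x)),
                            stations = seq(0, 100, 10))
  d <- make_plane_samples(analytic_flow_spec("parabolic", Q = 50), secs,
                          pressure_fun = function(x) -2 * x)
  en <- cumulative_loss(d, rho = rho_air)
  # deviation from the straight line through the endpoints is negligible
  line <- en$cum_loss[1] + (en$x - en$x[1]) / diff(range(en$x)) *
    (en$cum_loss[nrow(en)] - en$cum_loss[1])
  expect_lt(max(abs(en$cum_loss - line)), 1e-9 * max(en$cum_loss))
})

test_that("inconsistent station flowrates raise a conservation error", {
  secs <- uniform_sections(area = 100, stations = c(0, 50))
  d1 <- make_plane_samples(analytic_flow_spec("plug", Q = 392), secs)
  d2 <- make_plane_samples(analytic_flow_spec("plug", Q = 300), secs)
  bad <- structure(list(d1[[1]], d2[[2]]), class = "plane_dataset")
  expect_error(cumulative_loss(bad, rho = rho_air), "conservation")
})

test_that("resistance is zero for uniform lossless flow and matches Hagen-Poiseuille", {
  secs <- uniform_sections(area = 100, stations = c(0, 40, 80))
  d <- make_plane_samples(analytic_flow_spec("plug", Q = 392), secs)
  rs <- resistance_profile(d, Q = 392, rho = rho_air)
  expect_equal(rs$R, rep(0, 3), tolerance = 1e-12)

  # Poiseuille tube: R(L) = 8 mu L / (pi r^4), converted to Pa.s/mL
  r_mm <- 2; L_mm <- 100; mu <- 1.8e-5; Q <- 100  # mL/s
  A <- pi * r_mm^2
  U <- Q / A                                       # m/s
  dpdx_Pa_per_m <- 8 * mu * U / (r_mm * 1e-3)^2
  secs2 <- analytic_sections(function(x) rep(A, length(x)),
                             stations = seq(0, L_mm, 10), ntheta = 128)
  d2 <- make_plane_samples(analytic_flow_spec("parabolic", Q = Q), secs2,
                           pressure_fun = function(x) -dpdx_Pa_per_m * x * 1e-3)
  rs2 <- resistance_profile(d2, Q = Q, rho = rho_air)
  R_analytic <- 8 * mu * (L_mm * 1e-3) / (pi * (r_mm * 1e-3)^4) * 1e-6
  expect_equal(rs2$R[nrow(rs2)], R_analytic, tolerance = 0.01)
})

test_that("overall resistance of an orifice dataset equals dP_true / Q", {
  orf <- orifice_dataset(rms = 0.05)
  rs <- resistance_profile(orf$dataset, Q = 392, rho = rho_air)
  expect_equal(rs$R[nrow(rs)], orf$dp_true / 392, tolerance = 0.01)
  expect_equal(rs$R[1], 0)
  # static convention differs where the lumen area changes
  rs_static <- resistance_profile(orf$dataset, Q = 392, rho = rho_air,
                                  pressure = "static")
  i_throat <- which.min(abs(rs$x - orf$x_throat))
  expect_gt(abs(rs_static$R[i_throat] - rs$R[i_throat]), 0)
})

test_that("profile CSV writers emit the documented schemas", {
  orf <- orifice_dataset(rms = 0, n_snapshots = 1)
  en <- cumulative_loss(orf$dataset, rho = rho_air)
  rs <- resistance_profile(orf$dataset, Q = 392, rho = rho_air)
  dir <- withr::local_tempdir()
  f1 <- write_energy_profile_csv(en, file.path(dir, "e.csv"))
  f2 <- write_resistance_profile_csv(rs, file.path(dir, "r.csv"))
  expect_equal(names(utils::read.csv(file.path(dir, "e.csv"))),
               c("x_mm", "E_F_W", "cum_loss_W"))
  expect_equal(names(utils::read.csv(file.path(dir, "r.csv"))),
               c("x_mm", "R_Pa_per_mLs"))
})
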