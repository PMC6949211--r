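test_that("centerline resampling gives uniform arclength and preserves endpoints", {
  cl <- resample_centerline(rbind(c(0, 0, 0), c(0, 0, 10)), spacing = 1)
  expect_equal(nrow(cl$points), 11L)
  expect_equal(cl$arclength, 0:10, tolerance = 1e-9)
  expect_equal(cl$points[1, ], c(0, 0, 0))
  expect_equal(cl$points[11, ], c(0, 0, 10))
  expect_lt(max(abs(diff(cl$arclength) - 1)), 1e-6)

  # quarter circle, radius 10: arclength converges to 5*pi
  th <- seq(0, pi / 2, length.out = 2000)
  arc <- resample_centerline(cbind(10 * cos(th), 10 * sin(th), 0), spacing = 0.05)
  expect_equal(max(arc$arclength), 5 * pi, tolerance = 1e-4)

  expect_error(resample_centerline(rbind(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
  expect_error(resample_centerline(rbind(c(0, 0, 0), c(0, 0, 1)), spacing = 0),
               "spacing")
})

test_that("slicing frames are unit central-difference tangents", {
  straight <- resample_centerline(rbind(c(0, 0, 0), c(0, 0, 20)), spacing = 2)
  fr <- frames_along(straight)
  expect_true(all(abs(fr$normals[, 3] - 1) < 1e-12))
  expect_equal(nrow(fr$normals), nrow(straight$points))

  two <- centerline(rbind(c(0, 0, 0), c(1, 2, 2)))
  fr2 <- frames_along(two)
  expect_equal(fr2$normals[1, ], fr2$normals[2, ])
  expect_equal(sqrt(sum(fr2$normals[1, ]^2)), 1, tolerance = 1e-12)

  # planar arc: central differences align exactly with the analytic tangent
  th <- seq(0, pi / 2, length.out = 101)
  arc <- centerline(cbind(10 * cos(th), 10 * sin(th), 0))
  fr3 <- frames_along(arc)
  inner <- 2:100
  tans <- cbind(-sin(th[inner]), cos(th[inner]), 0)
  dots <- rowSums(fr3$normals[inner, ] * tans)
  expect_true(all(abs(abs(dots) - 1) < 1e-10))
  expect_equal(sqrt(rowSums(fr3$normals^2)), rep(1, 101), tolerance = 1e-12)
})

test_that("cylinder slices recover the circle area, with O(h^2) convergence", {
  r <- 10
  ns <- c(24, 48, 96)
  errs <- vapply(ns, function(n) {
    mesh <- cylinder_mesh(radius = r, ntheta = n)
    sec <- slice_area(mesh, c(0, 0, 20), c(0, 0, 1))
    abs(sec$area - pi * r^2)
  }, numeric(1))
  expect_lt(errs[3] / (pi * r^2), 0.001)
  rates <- log(errs[-3] / errs[-1]) / log(2)
  expect_true(all(rates > 1.9))
  # hydraulic diameter of a near-circle is close to 2r, and consistent
  sec <- slice_area(cylinder_mesh(radius = r, ntheta = 96), c(0, 0, 20), c(0, 0, 1))
  expect_equal(sec$hydraulic_diameter, 4 * sec$area / sec$perimeter,
               tolerance = 1e-12)
  expect_equal(sec$hydraulic_diameter, 2 * r, tolerance = 0.01)
})

test_that("oblique slices of a cylinder give the ellipse area", {
  mesh <- cylinder_mesh(radius = 10, length = 60, ntheta = 96)
  n <- c(0, sin(pi / 6), cos(pi / 6))
  sec <- slice_area(mesh, c(0, 0, 30), n)
  expect_equal(sec$area, 100 * pi / cos(pi / 6), tolerance = 0.005)
})

test_that("slicing outside the mesh raises an empty-section error", {
  mesh <- cylinder_mesh(radius = 5, length = 20, ntheta = 32)
  expect_error(slice_area(mesh, c(0, 0, 100), c(0, 0, 1)), "empty-section")
})

test_that("area profiles follow the generator's analytic area law", {
  aw <- default_airway()
  pr <- default_mesh_profile()
  an <- aw$area_fun(aw$centerline$arclength)
  expect_lt(max(abs(pr$A / an - 1)), 0.01)
  # carina alignment: x = arclength - offset, most superior most negative
  expect_equal(pr$x, aw$centerline$arclength - aw$imaged_range[2])
  pr0 <- area_profile(cylinder_mesh(radius = 5, length = 20, ntheta = 32),
                      resample_centerline(rbind(c(0, 0, 1), c(0, 0, 19)), 2),
                      carina_offset = 0)
  expect_equal(pr0$x, seq(0, 18, by = 2))          # raw arclength when offset 0
  expect_lt(diff(range(pr0$A)) / mean(pr0$A), 1e-9)  # uniform tube: constant A
})

test_that("local minima are located at the generator's dips", {
  x <- seq(-240, 0, by = 1)
  dip <- function(x0, depth, width) depth * exp(-(x - x0)^2 / (2 * width^2))
  A <- 300 * (1 - dip(-200, 0.3, 4) - dip(-135, 0.5, 4) - dip(-85, 0.6, 4))
  pr <- new_area_profile(x, A)
  m <- local_minima(pr, k = 3)
  expect_equal(m$x, c(-200, -135, -85))

  mono <- new_area_profile(1:10, seq(100, 10, length.out = 10))
  expect_equal(nrow(local_minima(mono, 3)), 0L)

  flat <- new_area_profile(1:11, c(9, 8, 7, 5, 5, 5, 5, 7, 8, 9, 10))
  mf <- local_minima(flat, 1)
  expect_equal(mf$x, 5.5)                           # midpoint of the flat run
  expect_equal(mf$A, 5)
})

test_that("constriction ratios reproduce the case-study arithmetic", {
  vprofile <- function(A_ref, A_min) {
    x <- seq(0, 100, by = 0.5)
    new_area_profile(x, A_ref - (A_ref - A_min) * exp(-(x - 50)^2 / 200))
  }
  m15 <- constriction_metrics(vprofile(117, 20.5), ref_station = 0)
  expect_lt(abs(100 * m15$ratio - 82.5), 0.05)
  m4 <- constriction_metrics(vprofile(148, 35.2), ref_station = 0)
  expect_lt(abs(100 * m4$ratio - 76.2), 0.05)
})

test_that("constricted length matches the Gaussian closed form", {
  A0 <- 117; c <- 0.825; sigma <- 12.49; x0 <- 0
  x <- seq(-80, 80, by = 0.05)
  pr <- new_area_profile(x, A0 * (1 - c * exp(-(x - x0)^2 / (2 * sigma^2))))
  m <- constriction_metrics(pr, ref_station = -80, threshold = 0.35)
  len_true <- 2 * sigma * sqrt(2 * log(c / 0.35))
  expect_equal(m$length, len_true, tolerance = 0.01)
  # length shrinks toward zero as the threshold approaches the dip depth
  l2 <- constriction_metrics(pr, ref_station = -80, threshold = 0.6)$length
  l3 <- constriction_metrics(pr, ref_station = -80, threshold = 0.8)$length
  l4 <- constriction_metrics(pr, ref_station = -80, threshold = 0.82)$length
  expect_true(m$length > l2 && l2 > l3 && l3 > l4 && l4 > 0)
  expect_equal(constriction_metrics(pr, ref_station = -80, threshold = 0.9)$length, 0)
})

test_that("constriction metrics are invariant under profile translation", {
  pr <- default_mesh_profile()
  aw <- default_airway()
  ref <- aw$imaged_range[1] - aw$imaged_range[2]
  m0 <- constriction_metrics(pr, ref_station = ref)
  m1 <- constriction_metrics(align_profile(pr, 37.5), ref_station = ref + 37.5)
  expect_equal(m1$ratio, m0$ratio, tolerance = 1e-12)
  expect_equal(m1$length, m0$length, tolerance = 1e-9)
  expect_equal(m1$x_min, m0$x_min + 37.5, tolerance = 1e-9)
})

test_that("degenerate and widened profiles are handled", {
  flat <- new_area_profile(0:10, rep(100, 11))
  m <- constriction_metrics(flat, ref_station = 0)
  expect_equal(m$ratio, 0)
  expect_equal(m$length, 0)
  # post-operative lumen everywhere wider than the pre-operative reference
  widened <- new_area_profile(0:10, c(100, 105, 110, 120, 130, 140, 150,
                                      140, 130, 120, 110))
  expect_warning(mw <- constriction_metrics(widened, ref_area = 90),
                 "widened")
  expect_lt(mw$ratio, 0)
  expect_true(mw$widened)
  expect_equal(mw$length, 0)
  expect_error(constriction_metrics(flat, ref_station = 99), "ref_station")
  expect_error(constriction_metrics(flat), "ref_station or ref_area")
})

test_that("profile alignment round-trips and landmarks can be co-registered", {
  pr <- new_area_profile(seq(0, 50, 5), 100 + seq(0, 50, 5))
  expect_equal(align_profile(pr, 0), pr)
  expect_equal(align_profile(align_profile(pr, 5), -5), pr)
  # two copies of one profile shifted to share a landmark coincide there
  a <- align_profile(pr, -20)
  b <- align_profile(pr, -20)
  expect_equal(a$x[3], b$x[3])
  expect_equal(a$A, b$A)
})

test_that("geometry CSV and STL round trips preserve the data", {
  dir <- withr::local_tempdir()
  cl <- resample_centerline(rbind(c(0, 1, 2), c(3, 4, 5), c(3, 4, 9)), 0.5)
  f1 <- file.path(dir, "cl.csv")
  write_centerline_csv(cl, f1)
  cl2 <- read_centerline_csv(f1)
  expect_equal(cl2$points, unname(cl$points), tolerance = 1e-9,
               ignore_attr = TRUE)

  pr <- new_area_profile(0:5, c(10, 9, 8, 7, 8, 9))
  f2 <- file.path(dir, "prof.csv")
  write_area_profile_csv(pr, f2)
  expect_equal(read_area_profile_csv(f2), pr, tolerance = 1e-9)

  mesh <- cylinder_mesh(radius = 5, length = 20, ntheta = 24)
  f3 <- file.path(dir, "tube.stl")
  write_stl(mesh, f3)
  mesh2 <- read_stl(f3)
  expect_true(is_watertight(mesh2))
  a1 <- slice_area(mesh, c(0, 0, 10), c(0, 0, 1))$area
  a2 <- slice_area(mesh2, c(0, 0, 10), c(0, 0, 1))$area
  expect_equal(a2, a1, tolerance = 1e-5)
})

test_that("binary STL files are read", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "tet.stl")
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  con <- file(f, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(faces))) {
    writeBin(rep(0, 3), con, size = 4, endian = "little")    # normal
    for (j in faces[i, ]) writeBin(v[j, ], con, size = 4, endian = "little")
    writeBin(raw(2), con)                                     # attribute count
  }
  close(con)
  m <- read_stl(f)
  expect_equal(nrow(m$faces), 4L)
  expect_equal(nrow(m$vertices), 4L)
  expect_true(is_watertight(m))
})
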