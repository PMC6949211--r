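#' Airway centerline
#'
#' An ordered 3D polyline (mm) with cumulative arclength and optional named
#' anatomical landmark stations (e.g. `carina_offset`, `first_ring_station`,
#' `glottis_station`, all in mm of arclength).
#'
#' @param points numeric `n x 3` matrix of ordered points (mm).
#' @param landmarks optional named numeric vector of arclength stations (mm).
#' @return an object of class `centerline` with fields `points`, `arclength`,
#'   `landmarks`.
#' @export
centerline <- function(points, landmarks = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    .stopf("invalid-input: a centerline needs at least two 3D points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0))
    .stopf("invalid-input: repeated consecutive centerline points")
  arc <- c(0, cumsum(seg))
  if (!is.null(landmarks)) {
    if (any(landmarks < 0 | landmarks > arc[length(arc)]))
      .stopf("invalid-input: landmark station outside [0, total length]")
  }
  structure(list(points = points, arclength = arc, landmarks = landmarks),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline: %d points, length %.2f mm>\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' Resample a polyline to uniform arclength spacing
#'
#' The polyline is re-parameterised by cumulative chord length and sampled at
#' `n = round(L/spacing) + 1` equally spaced stations, so both endpoints are
#' preserved and the realised spacing is within one part in `n` of the request.
#'
#' @param points numeric `n x 3` matrix of ordered points (mm), or a
#'   [centerline()].
#' @param spacing target station spacing (mm), default 1 mm (comparable to the
#'   finest CT slice thickness in routine airway scans).
#' @param landmarks optional named landmark stations (mm), carried through.
#' @return a [centerline()] with equally spaced points.
#' @export
resample_centerline <- function(points, spacing = 1, landmarks = NULL) {
  if (inherits(points, "centerline")) {
    if (is.null(landmarks)) landmarks <- points$landmarks
    points <- points$points
  }
  points <- as.matrix(points)
  if (nrow(points) < 2L) .stopf("invalid-input: need at least two points")
  if (spacing <= 0) .stopf("invalid-input: spacing must be positive")
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L)
    .stopf("invalid-input: degenerate (zero-length) polyline")
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  n <- max(2L, as.integer(round(L / spacing)) + 1L)
  s <- seq(0, L, length.out = n)
  out <- vapply(1:3, function(j) stats::approx(arc, points[, j], xout = s)$y,
                numeric(n))
  centerline(out, landmarks = landmarks)
}

#' Slicing frames along a centerline
#'
#' One (origin, unit normal) pair per centerline point.  Normals are the local
#' tangents estimated by central differences (one-sided at the ends), so the
#' slicing planes are normal to the local centerline direction.
#'
#' @param cl a [centerline()].
#' @return list with `origins` (`n x 3`) and `normals` (`n x 3`, unit rows).
#' @export
frames_along <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  n <- nrow(p)
  tang <- matrix(0, n, 3)
  if (n == 2L) {
    tang[1, ] <- tang[2, ] <- p[2, ] - p[1, ]
  } else {
    tang[1, ] <- p[2, ] - p[1, ]
    tang[n, ] <- p[n, ] - p[n - 1, ]
    tang[2:(n - 1), ] <- p[3:n, ] - p[1:(n - 2), ]
  }
  tang <- tang / sqrt(rowSums(tang^2))
  list(origins = p, normals = tang)
}

#' Cross-section of a lumen surface
#'
#' Intersects a watertight mesh with a plane and keeps the closed intersection
#' loop whose centroid is nearest `near_point` (near branches several loops can
#' appear; the centerline's own point disambiguates).  Area is the planar
#' polygon area of the loop, perimeter its length, and the hydraulic diameter
#' `4 * area / perimeter`.
#'
#' @param mesh a [tri_mesh()], coordinates in mm.
#' @param origin point on the slicing plane (mm).
#' @param normal plane normal (normalised internally).
#' @param near_point 3D point used to select among multiple loops; defaults to
#'   `origin`.
#' @param station arclength station label (mm) stored on the result.
#' @return an object of class `cross_section` with fields `station`, `origin`,
#'   `normal`, `loops`, `area` (mm^2), `perimeter` (mm), `hydraulic_diameter`
#'   (mm), `centroid`.
#' @export
slice_area <- function(mesh, origin, normal, near_point = origin,
                       station = NA_real_) {
  normal <- normal / sqrt(sum(normal^2))
  loops <- .slice_mesh_loops(mesh, origin, normal)
  mets <- lapply(loops, .loop_metrics, normal = normal)
  d2 <- vapply(mets, function(m) sum((m$centroid - near_point)^2), numeric(1))
  i <- which.min(d2)
  m <- mets[[i]]
  if (m$area <= 0) .stopf("topology: degenerate intersection loop")
  structure(list(station = station, origin = origin, normal = normal,
                 loops = loops[i], area = m$area, perimeter = m$perimeter,
                 hydraulic_diameter = 4 * m$area / m$perimeter,
                 centroid = m$centroid),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section: s = %.2f mm, A = %.2f mm^2, D_h = %.2f mm>\n",
              x$station, x$area, x$hydraulic_diameter))
  invisible(x)
}

#' Cross-sectional area profile along a centerline
#'
#' Slices the mesh at every centerline station with the [frames_along()]
#' planes.  Stations are reported as signed distance from the carina origin:
#' `x = arclength - carina_offset`, so the most superior station is the most
#' negative and the carina sits at `x = 0`.
#'
#' @param mesh a [tri_mesh()].
#' @param cl a [centerline()] (usually resampled to ~1 mm spacing).
#' @param carina_offset arclength of the carina station (mm); 0 keeps raw
#'   arclength.
#' @return an `area_profile`: data.frame with columns `x` (mm) and `A` (mm^2).
#' @export
area_profile <- function(mesh, cl, carina_offset = 0) {
  fr <- frames_along(cl)
  n <- nrow(fr$origins)
  A <- numeric(n)
  for (i in seq_len(n)) {
    sec <- tryCatch(
      slice_area(mesh, fr$origins[i, ], fr$normals[i, ],
                 near_point = fr$origins[i, ], station = cl$arclength[i]),
      error = function(e) .stopf("station %d (s = %.2f mm): %s",
                                 i, cl$arclength[i], conditionMessage(e)))
    A[i] <- sec$area
  }
  new_area_profile(cl$arclength - carina_offset, A)
}

#' Construct an area profile
#'
#' @param x signed stations (mm), strictly increasing; negative = superior to
#'   the carina.
#' @param A lumen areas (mm^2), all positive.
#' @return data.frame of class `area_profile`.
#' @export
new_area_profile <- function(x, A) {
  if (any(diff(x) <= 0)) .stopf("invalid-input: stations must strictly increase")
  if (any(A <= 0)) .stopf("invalid-input: areas must be positive")
  structure(data.frame(x = x, A = A),
            class = c("area_profile", "data.frame"))
}

#' Shift an area profile along the airway axis
#'
#' Used to translate profiles from different scans to a common (estimated)
#' carina origin; areas are untouched.
#'
#' @param profile an `area_profile`.
#' @param offset shift added to `x` (mm).
#' @return the shifted `area_profile`.
#' @export
align_profile <- function(profile, offset) {
  new_area_profile(profile$x + offset, profile$A)
}

#' Interior local minima of an area profile
#'
#' Finds interior local minima (runs of equal values count once; a
#' flat-bottomed dip is reported at the midpoint of the flat run), then keeps
#' the `k` with the smallest areas (ties broken toward smaller `x`) and returns
#' them sorted by station.
#'
#' @param profile an `area_profile` with at least 3 stations.
#' @param k number of minima requested; fewer are returned if fewer exist.
#' @return data.frame with columns `x`, `A`, possibly 0 rows.
#' @export
local_minima <- function(profile, k = 3L) {
  if (nrow(profile) < 3L) .stopf("invalid-input: profile needs >= 3 stations")
  x <- profile$x; A <- profile$A
  r <- rle(A)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  mins <- list()
  for (j in seq_len(nr)) {
    if (j == 1L || j == nr) next                      # interior only
    if (r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1]) {
      mins[[length(mins) + 1L]] <-
        c(x = (x[starts[j]] + x[ends[j]]) / 2, A = r$values[j])
    }
  }
  if (length(mins) == 0L)
    return(data.frame(x = numeric(0), A = numeric(0)))
  m <- as.data.frame(do.call(rbind, mins))
  m <- m[order(m$A, m$x), , drop = FALSE]
  m <- utils::head(m, k)
  m <- m[order(m$x), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Constriction metrics of an area profile
#'
#' Reference area `A_ref` is linearly interpolated at `ref_station` (by
#' convention the first tracheal ring).  The constriction ratio is
#' `(A_ref - A_min)/A_ref`; the constricted length is the extent of the
#' contiguous run containing the minimum where `A <= (1 - threshold) * A_ref`,
#' with the endpoints located by linear interpolation in `x`.
#'
#' A post-operative lumen can exceed the reference area (e.g. when judged
#' against a reference area taken from an earlier scan via `ref_area`); the
#' ratio is then negative and flagged rather than an error.
#'
#' @param profile an `area_profile`.
#' @param ref_station station of the reference (first tracheal ring) plane, in
#'   the profile's `x` coordinate (mm); `A_ref` is interpolated there.
#' @param ref_area alternatively, a fixed reference area (mm^2), e.g. the
#'   first-ring area of a different scan of the same subject; overrides
#'   `ref_station`.
#' @param threshold area-reduction fraction defining "constricted";
#'   default 0.35 (the conventional 35% reduction rule).
#' @return object of class `constriction_metrics`: list with `A_ref`, `A_min`,
#'   `x_min`, `ratio`, `length`, `threshold`, `widened` (flag).
#' @export
constriction_metrics <- function(profile, ref_station = NULL, ref_area = NULL,
                                 threshold = 0.35) {
  if (threshold <= 0 || threshold >= 1)
    .stopf("invalid-input: threshold must be in (0, 1)")
  x <- profile$x; A <- profile$A
  if (is.null(ref_area)) {
    if (is.null(ref_station))
      .stopf("invalid-input: give one of ref_station or ref_area")
    if (ref_station < min(x) || ref_station > max(x))
      .stopf("invalid-input: ref_station outside the profile")
    A_ref <- stats::approx(x, A, xout = ref_station)$y
  } else {
    if (ref_area <= 0) .stopf("invalid-input: ref_area must be positive")
    A_ref <- ref_area
  }
  i_min <- which.min(A)
  A_min <- A[i_min]
  x_min <- x[i_min]
  ratio <- (A_ref - A_min) / A_ref
  widened <- A_min > A_ref
  if (widened)
    warning("minimum area exceeds the reference area (widened lumen); ",
            "ratio reported negative", call. = FALSE)

  level <- (1 - threshold) * A_ref
  len <- 0
  if (A_min <= level) {
    lo <- i_min
    while (lo > 1L && A[lo - 1L] <= level) lo <- lo - 1L
    hi <- i_min
    while (hi < length(A) && A[hi + 1L] <= level) hi <- hi + 1L
    x_lo <- if (lo == 1L) x[1L] else {
      t <- (level - A[lo - 1L]) / (A[lo] - A[lo - 1L])
      x[lo - 1L] + t * (x[lo] - x[lo - 1L])
    }
    x_hi <- if (hi == length(A)) x[length(A)] else {
      t <- (level - A[hi]) / (A[hi + 1L] - A[hi])
      x[hi] + t * (x[hi + 1L] - x[hi])
    }
    len <- x_hi - x_lo
  }
  structure(list(A_ref = A_ref, A_min = A_min, x_min = x_min, ratio = ratio,
                 length = len, threshold = threshold, widened = widened),
            class = "constriction_metrics")
}

#' @export
print.constriction_metrics <- function(x, ...) {
  cat(sprintf(
    "<constriction: A_ref %.1f mm^2, A_min %.1f mm^2 at x = %.1f mm,\n  ratio %.1f%%, length %.1f mm (threshold %.0f%%)%s>\n",
    x$A_ref, x$A_min, x$x_min, 100 * x$ratio, x$length, 100 * x$threshold,
    if (x$widened) ", widened lumen" else ""))
  invisible(x)
}

#' Read / write centerline and profile CSV files
#'
#' Centerlines: columns `x,y,z` in mm.  Profiles: columns `x_mm,area_mm2`.
#'
#' @param path CSV file path.
#' @param cl,profile objects to write.
#' @return the read object, or `path` invisibly for writers.
#' @name geometry_io
NULL

#' @rdname geometry_io
#' @export
read_centerline_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(d)))
    .stopf("%s: expected columns x,y,z", path)
  centerline(as.matrix(d[, c("x", "y", "z")]))
}

#' @rdname geometry_io
#' @export
write_centerline_csv <- function(cl, path) {
  d <- as.data.frame(cl$points)
  names(d) <- c("x", "y", "z")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname geometry_io
#' @export
read_area_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_mm", "area_mm2") %in% names(d)))
    .stopf("%s: expected columns x_mm,area_mm2", path)
  new_area_profile(d$x_mm, d$area_mm2)
}

#' @rdname geometry_io
#' @export
write_area_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(x_mm = profile$x, area_mm2 = profile$A),
                   path, row.names = FALSE)
  invisible(path)
}
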