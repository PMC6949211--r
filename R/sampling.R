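#' Time-resolved flow samples on one cross-sectional plane
#'
#' All snapshots share one point set.  Units: points mm, quadrature weights
#' mm^2 (summing to the section area within 0.5%), velocity m/s, pressure Pa,
#' time s.  With these units `sum(weights * (u . n))` is directly a flowrate
#' in mL/s.
#'
#' @param points `n x 3` sample locations (mm).
#' @param weights quadrature areas (mm^2), one per point.
#' @param normal unit plane normal (flow-positive direction).
#' @param station station coordinate of the plane (mm).
#' @param area section area (mm^2).
#' @param times snapshot times (s), uniformly spaced.
#' @param u velocity array `n x 3 x n_t` (m/s).
#' @param p static pressure matrix `n x n_t` (Pa).
#' @param f optional radial fraction per point (generator metadata).
#' @return an object of class `plane_series`.
#' @export
plane_series <- function(points, weights, normal, station, area, times, u, p,
                         f = NULL) {
  n <- nrow(points)
  nt <- length(times)
  if (length(weights) != n) .stopf("invalid-input: weights/points mismatch")
  if (!all(dim(u) == c(n, 3L, nt))) .stopf("invalid-input: u must be n x 3 x n_t")
  if (!all(dim(p) == c(n, nt))) .stopf("invalid-input: p must be n x n_t")
  if (abs(sum(weights) - area) > 0.005 * area)
    .stopf("invalid-input: quadrature weights must sum to the section area within 0.5%%")
  if (nt > 1L) {
    dts <- diff(times)
    if (max(abs(dts - dts[1])) > 1e-9 * max(dts))
      .stopf("invalid-input: snapshot times must be uniformly spaced")
  }
  structure(list(points = points, weights = weights,
                 normal = normal / sqrt(sum(normal^2)), station = station,
                 area = area, times = times, u = u, p = p, f = f),
            class = "plane_series")
}

#' @export
print.plane_series <- function(x, ...) {
  cat(sprintf("<plane_series: s = %.2f mm, %d points x %d snapshots>\n",
              x$station, nrow(x$points), length(x$times)))
  invisible(x)
}

#' Time-average a plane series
#'
#' Snapshots before `discard_before` are dropped (start-up transients); the
#' arithmetic mean of velocity and pressure is taken over the retained window,
#' and the pointwise fluctuation RMS is the root-mean-square of the velocity
#' *vector* deviation, `sqrt(mean_t |u - ubar|^2)`.
#'
#' @param series a [plane_series()].
#' @param discard_before snapshots with `time < discard_before` are excluded
#'   (s).  Default 0 retains everything.
#' @return a `mean_plane_field`: list with `mean_u` (`n x 3`), `mean_p`,
#'   `fluctuation_rms`, `n_averaged`, plus the plane geometry (`points`,
#'   `weights`, `normal`, `station`, `area`).
#' @export
time_average <- function(series, discard_before = 0) {
  stopifnot(inherits(series, "plane_series"))
  keep <- which(series$times >= discard_before)
  if (length(keep) == 0L)
    .stopf("empty-window: all snapshots are before discard_before = %g s",
           discard_before)
  u <- series$u[, , keep, drop = FALSE]
  p <- series$p[, keep, drop = FALSE]
  nt <- length(keep)
  mean_u <- apply(u, c(1, 2), mean)
  mean_p <- rowMeans(p)
  dev2 <- 0
  for (t in seq_len(nt)) dev2 <- dev2 + rowSums((u[, , t] - mean_u)^2)
  rms <- sqrt(dev2 / nt)
  structure(list(mean_u = mean_u, mean_p = mean_p, fluctuation_rms = rms,
                 n_averaged = nt, points = series$points,
                 weights = series$weights, normal = series$normal,
                 station = series$station, area = series$area),
            class = "mean_plane_field")
}

#' @export
print.mean_plane_field <- function(x, ...) {
  cat(sprintf("<mean_plane_field: s = %.2f mm, %d points, %d snapshots averaged>\n",
              x$station, nrow(x$points), x$n_averaged))
  invisible(x)
}

.as_mean_field <- function(x, discard_before = 0) {
  if (inherits(x, "mean_plane_field")) x else time_average(x, discard_before)
}

#' Flowrate through a plane
#'
#' `Q = sum(weights * (ubar . n))` in mL/s (weights mm^2, velocity m/s).  The
#' sign follows the plane normal's orientation.
#'
#' @param field a `mean_plane_field` (or a [plane_series()], averaged with
#'   `discard_before`).
#' @param discard_before passed to [time_average()] when `field` is a series.
#' @return flowrate in mL/s.
#' @export
plane_flowrate <- function(field, discard_before = 0) {
  field <- .as_mean_field(field, discard_before)
  sum(field$weights * as.vector(field$mean_u %*% field$normal))
}

#' Cross-section averaged turbulence intensity
#'
#' Area-weighted mean of the pointwise fluctuation RMS, normalised by a
#' reference velocity (conventionally the bulk velocity at a named reference
#' plane, e.g. the first tracheal ring).
#'
#' @param field a `mean_plane_field` (or series).
#' @param u_ref reference velocity (m/s), must be positive.
#' @param discard_before passed to [time_average()] when needed.
#' @return dimensionless turbulence intensity.
#' @export
turbulence_intensity <- function(field, u_ref, discard_before = 0) {
  if (!is.numeric(u_ref) || u_ref <= 0)
    .stopf("invalid-reference: u_ref must be positive")
  field <- .as_mean_field(field, discard_before)
  sum(field$weights * field$fluctuation_rms) / sum(field$weights) / u_ref
}

#' Read / write plane-sample datasets as CSV
#'
#' Two plain-text files describe a dataset: a samples file with columns
#' `station_mm,time_s,px,py,pz,u,v,w,p,weight_mm2` (mm, s, m/s, Pa, mm^2) and
#' a sections file with columns `station_mm,nx,ny,nz,area_mm2` carrying each
#' plane's normal and area.
#'
#' @param dataset a `plane_dataset` (list of [plane_series()]).
#' @param samples_path,sections_path CSV file paths.
#' @return the dataset (readers) or `samples_path` invisibly (writers).
#' @name plane_io
NULL

#' @rdname plane_io
#' @export
write_plane_samples <- function(dataset, samples_path, sections_path) {
  rows <- lapply(dataset, function(s) {
    nt <- length(s$times)
    n <- nrow(s$points)
    do.call(rbind, lapply(seq_len(nt), function(t)
      data.frame(station_mm = s$station, time_s = s$times[t],
                 px = s$points[, 1], py = s$points[, 2], pz = s$points[, 3],
                 u = s$u[, 1, t], v = s$u[, 2, t], w = s$u[, 3, t],
                 p = s$p[, t], weight_mm2 = s$weights)))
  })
  utils::write.csv(do.call(rbind, rows), samples_path, row.names = FALSE)
  secs <- do.call(rbind, lapply(dataset, function(s)
    data.frame(station_mm = s$station, nx = s$normal[1], ny = s$normal[2],
               nz = s$normal[3], area_mm2 = s$area)))
  utils::write.csv(secs, sections_path, row.names = FALSE)
  invisible(samples_path)
}

#' @rdname plane_io
#' @export
read_plane_samples <- function(samples_path, sections_path) {
  d <- utils::read.csv(samples_path)
  need <- c("station_mm", "time_s", "px", "py", "pz", "u", "v", "w", "p",
            "weight_mm2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("%s: missing column(s) %s", samples_path, paste(miss, collapse = ", "))
  secs <- utils::read.csv(sections_path)
  need2 <- c("station_mm", "nx", "ny", "nz", "area_mm2")
  miss2 <- setdiff(need2, names(secs))
  if (length(miss2))
    .stopf("%s: missing column(s) %s", sections_path, paste(miss2, collapse = ", "))
  stations <- sort(unique(d$station_mm))
  series <- lapply(stations, function(st) {
    ds <- d[d$station_mm == st, ]
    times <- sort(unique(ds$time_s))
    d0 <- ds[ds$time_s == times[1], ]
    n <- nrow(d0)
    u <- array(0, c(n, 3L, length(times)))
    p <- matrix(0, n, length(times))
    for (t in seq_along(times)) {
      dt_ <- ds[ds$time_s == times[t], ]
      u[, , t] <- as.matrix(dt_[, c("u", "v", "w")])
      p[, t] <- dt_$p
    }
    sec <- secs[match(st, secs$station_mm), ]
    plane_series(points = as.matrix(d0[, c("px", "py", "pz")]),
                 weights = d0$weight_mm2,
                 normal = c(sec$nx, sec$ny, sec$nz), station = st,
                 area = sec$area_mm2, times = times, u = u, p = p)
  })
  structure(series, class = "plane_dataset")
}
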