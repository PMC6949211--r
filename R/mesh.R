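#' Triangle surface mesh
#'
#' Minimal container for a triangulated surface: an `n x 3` vertex matrix (mm)
#' and an `m x 3` integer face matrix indexing rows of `vertices`.
#'
#' @param vertices numeric matrix, one 3D point (mm) per row.
#' @param faces integer matrix, one triangle (vertex indices) per row.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) .stopf("vertices must be an n x 3 matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    .stopf("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that every mesh edge is shared by exactly two faces
#'
#' @param mesh a [tri_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "airwayflux") {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  n <- .cross(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  block <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(block, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an STL surface (ASCII or binary)
#'
#' Duplicate vertices are merged so that shared triangle edges are represented
#' once, which the slicing and watertightness operations rely on.
#'
#' @param path STL file path.
#' @return a [tri_mesh()].
#' @export
read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 80L)
  head_txt <- rawToChar(hdr[hdr >= as.raw(32) & hdr < as.raw(127)])
  tri <- if (grepl("^\\s*solid", head_txt) && .looks_ascii_stl(path)) {
    .read_stl_ascii(path)
  } else {
    .read_stl_binary(path)
  }
  .mesh_from_triangle_soup(tri)
}

.looks_ascii_stl <- function(path) {
  # binary STL may still start with "solid"; ASCII must contain "facet"
  txt <- suppressWarnings(readLines(path, n = 5L))
  any(grepl("facet|endsolid", txt))
}

.read_stl_ascii <- function(path) {
  txt <- readLines(path)
  vlines <- grep("^\\s*vertex", txt, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(w)
    as.numeric(w[2:4])))
  if (nrow(nums) %% 3L != 0L) .stopf("malformed ASCII STL: %s", path)
  nums
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n = nfac * 50L)
  m <- matrix(rec, nrow = 50L)
  tri <- matrix(0, nrow = 3L * nfac, ncol = 3L)
  for (k in 1:3) {                     # vertex k of each facet
    off <- 12L * k                     # skip normal (12 bytes) + previous verts
    for (j in 1:3) {
      b <- m[off + (4L * (j - 1L) + 1L):(4L * (j - 1L) + 4L), , drop = FALSE]
      tri[seq(k, by = 3L, length.out = nfac), j] <-
        readBin(as.vector(b), "double", n = nfac, size = 4L, endian = "little")
    }
  }
  tri
}

.mesh_from_triangle_soup <- function(tri) {
  key <- apply(round(tri, 6L), 1L, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Orthonormal in-plane basis for a unit normal.
.plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Intersect a mesh with a plane. Returns a list of closed loops (each a k x 3
# matrix of points in order). Intersection points are computed once per mesh
# edge (canonical orientation), so loop chaining is exact integer matching.
.slice_mesh_loops <- function(mesh, origin, normal) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector((v - matrix(origin, nrow(v), 3, byrow = TRUE)) %*% normal)
  scale <- max(apply(v, 2, function(z) diff(range(z))), 1)
  eps <- 1e-9 * scale
  d[abs(d) < eps] <- eps                 # nudge on-plane vertices to one side
  s <- matrix(d[f] > 0, ncol = 3L)
  cut <- which(rowSums(s) %in% c(1L, 2L))
  if (length(cut) == 0L)
    .stopf("empty-section: plane does not intersect the mesh")

  seg_a <- integer(0); seg_b <- integer(0)    # crossing-edge ids per face
  edge_key <- character(0)
  edge_pts <- list()
  ekey <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  epoint <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    t <- d[lo] / (d[lo] - d[hi])
    v[lo, ] + t * (v[hi, ] - v[lo, ])
  }
  edges <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  keys <- new.env(parent = emptyenv())
  pts <- list(); kid <- 0L
  get_eid <- function(i, j) {
    k <- ekey(i, j)
    id <- keys[[k]]
    if (is.null(id)) {
      kid <<- kid + 1L
      keys[[k]] <- kid
      pts[[kid]] <<- epoint(i, j)
      id <- kid
    }
    id
  }
  for (fi in cut) {
    tr <- f[fi, ]
    ds <- d[tr] > 0
    ids <- integer(0)
    for (e in edges) {
      if (ds[e[1]] != ds[e[2]]) ids <- c(ids, get_eid(tr[e[1]], tr[e[2]]))
    }
    if (length(ids) == 2L) { seg_a <- c(seg_a, ids[1]); seg_b <- c(seg_b, ids[2]) }
  }
  nseg <- length(seg_a)
  if (nseg == 0L) .stopf("empty-section: plane does not intersect the mesh")

  # adjacency: edge id -> incident segments
  inc <- vector("list", kid)
  for (si in seq_len(nseg)) {
    inc[[seg_a[si]]] <- c(inc[[seg_a[si]]], si)
    inc[[seg_b[si]]] <- c(inc[[seg_b[si]]], si)
  }
  if (any(lengths(inc) != 2L))
    .stopf("topology: open intersection contour (mesh not closed near the plane)")

  used <- rep(FALSE, nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    cur <- start; enter <- seg_a[start]
    loop_ids <- integer(0)
    repeat {
      used[cur] <- TRUE
      exit <- if (seg_a[cur] == enter) seg_b[cur] else seg_a[cur]
      loop_ids <- c(loop_ids, exit)
      nxt <- setdiff(inc[[exit]], cur)
      if (used[nxt]) break
      cur <- nxt; enter <- exit
    }
    loops[[length(loops) + 1L]] <-
      do.call(rbind, pts[c(loop_ids[length(loop_ids)], loop_ids[-length(loop_ids)])])
  }
  loops
}

# Planar polygon area / perimeter / centroid from an ordered 3D loop.
.loop_metrics <- function(loop, normal) {
  b <- .plane_basis(normal)
  ref <- loop[1, ]
  rel <- sweep(loop, 2, ref)
  x <- as.vector(rel %*% b$e1)
  y <- as.vector(rel %*% b$e2)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a2 <- sum(cr)
  area <- abs(a2) / 2
  if (area > 0) {
    cx <- sum((x + xn) * cr) / (3 * a2)
    cy <- sum((y + yn) * cr) / (3 * a2)
  } else {
    cx <- mean(x); cy <- mean(y)
  }
  centroid <- ref + cx * b$e1 + cy * b$e2
  per <- sum(sqrt(rowSums((loop[c(2:nrow(loop), 1), ] - loop)^2)))
  list(area = area, perimeter = per, centroid = centroid)
}
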