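#' Triangulated surface mesh
#'
#' Vertices in world mm plus triangle faces (1-based vertex indices
#' internally). For brain-shift correction the mesh must be closed: every
#' edge shared by exactly two faces.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces",
      if (is_closed(x)) ", closed" else "", "\n", sep = "")
  invisible(x)
}

#' Is the mesh closed (every edge shared by exactly two faces)?
#'
#' @param mesh A [surface_mesh()].
#' @return Logical scalar.
#' @export
is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Point-in-mesh test by generalized winding number
#'
#' Sums the signed solid angle of every face as seen from the query point
#' (van Oosterom-Strackee); a point is interior when the total divided by
#' 4*pi exceeds 0.5. Robust to glancing ray intersections on coarse meshes.
#'
#' @param mesh A closed [surface_mesh()].
#' @param p World point(s), length-3 vector or n x 3 matrix (mm).
#' @return Logical vector, `TRUE` for interior points.
#' @export
is_inside <- function(mesh, p) {
  if (!is_closed(mesh)) {
    stop("mesh is not closed: winding-number containment undefined",
         call. = FALSE)
  }
  abs(winding_number(mesh, p)) > 0.5
}

winding_number <- function(mesh, p) {
  pts <- as_points(p)
  fc <- face_corners(mesh)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    a <- sweep(fc$a, 2, pts[i, ])
    b <- sweep(fc$b, 2, pts[i, ])
    c <- sweep(fc$c, 2, pts[i, ])
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c^2))
    num <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
           a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
           a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc +
           rowSums(a * c) * lb + rowSums(b * c) * la
    out[i] <- sum(2 * atan2(num, den)) / (4 * pi)
  }
  out
}

#' Exact nearest point on a triangulated surface
#'
#' For each query point returns the closest point on the surface itself —
#' face interior, edge, or vertex — not merely the nearest vertex, by
#' minimizing exact point-triangle distance over all faces.
#'
#' @param mesh A [surface_mesh()] with at least one face.
#' @param p World point(s), length-3 vector or n x 3 matrix (mm).
#' @return n x 3 matrix of surface points (mm).
#' @export
project_to_surface <- function(mesh, p) {
  if (nrow(mesh$faces) == 0L) {
    stop("mesh has no faces: cannot project", call. = FALSE)
  }
  pts <- as_points(p)
  fc <- face_corners(mesh)
  out <- matrix(NA_real_, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    cp <- closest_point_on_triangles(pts[i, ], fc$a, fc$b, fc$c)
    d2 <- rowSums(sweep(cp, 2, pts[i, ])^2)
    out[i, ] <- cp[which.min(d2), ]
  }
  out
}

# Vectorized closest point on each triangle (a,b,c rows) to point p.
# Ericson, Real-Time Collision Detection, sec. 5.1.5, vectorized over faces.
closest_point_on_triangles <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp_ <- sweep(-c, 2, p, "+")
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)

  n <- nrow(a)
  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)

  set_rows <- function(rows, val) {
    if (any(rows)) {
      res[rows, ] <<- val[rows, , drop = FALSE]
      done[rows] <<- TRUE
    }
  }

  # vertex regions
  set_rows(!done & d1 <= 0 & d2 <= 0, a)
  set_rows(!done & d3 >= 0 & d4 <= d3, b)
  set_rows(!done & d6 >= 0 & d5 <= d6, c)

  # edge AB
  vc <- d1 * d4 - d3 * d2
  rows <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(rows)) {
    v <- d1 / (d1 - d3)
    set_rows(rows, a + ab * v)
  }
  # edge AC
  vb <- d5 * d2 - d1 * d6
  rows <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(rows)) {
    w <- d2 / (d2 - d6)
    set_rows(rows, a + ac * w)
  }
  # edge BC
  va <- d3 * d6 - d5 * d4
  rows <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(rows)) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    set_rows(rows, b + (c - b) * w)
  }
  # face interior
  rows <- !done
  if (any(rows)) {
    denom <- va + vb + vc
    v <- vb / denom; w <- vc / denom
    set_rows(rows, a + ab * v + ac * w)
  }
  res
}
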