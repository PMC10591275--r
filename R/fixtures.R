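#' Ground-truth contact trajectory (straight line or circular arc)
#'
#' Generates `n` points with exact arc-length spacing along a straight line
#' (`curvature_radius = Inf`) or a circular arc of the given radius lying in
#' the plane orthogonal to `plane_normal`. The first point is `start` and
#' the initial tangent is `direction`. Shafts bend gently
#' (`curvature_radius` tens of mm); subdural strips wrapping the occipital
#' pole bend far more.
#'
#' @param start World start point (mm).
#' @param direction Initial tangent (need not be unit length).
#' @param n Number of contacts (>= 2).
#' @param spacing Arc-length spacing in mm (> 0).
#' @param curvature_radius Radius of curvature in mm, or `Inf` for straight.
#' @param plane_normal Normal of the bending plane (ignored when straight).
#' @return n x 3 matrix of world points.
#' @export
make_trajectory <- function(start, direction, n, spacing,
                            curvature_radius = Inf,
                            plane_normal = c(0, 0, 1)) {
  stopifnot(n >= 2, spacing > 0)
  d <- as.numeric(direction)
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("direction must be nonzero", call. = FALSE)
  d <- d / len
  start <- as.numeric(start)
  if (!is.finite(curvature_radius)) {
    s <- (seq_len(n) - 1) * spacing
    return(cbind(start[1] + s * d[1], start[2] + s * d[2],
                 start[3] + s * d[3]))
  }
  if (curvature_radius <= 0) {
    stop("curvature_radius must be positive or Inf", call. = FALSE)
  }
  b <- as.numeric(plane_normal)
  b <- b - sum(b * d) * d  # ensure orthogonal to tangent
  lb <- sqrt(sum(b^2))
  if (lb < 1e-12) stop("plane_normal is parallel to direction", call. = FALSE)
  b <- b / lb
  u <- c(b[2] * d[3] - b[3] * d[2],   # in-plane normal = b x d
         b[3] * d[1] - b[1] * d[3],
         b[1] * d[2] - b[2] * d[1])
  center <- start + curvature_radius * u
  theta <- (seq_len(n) - 1) * spacing / curvature_radius
  t(vapply(theta, function(th) {
    center - curvature_radius * cos(th) * u + curvature_radius * sin(th) * d
  }, numeric(3)))
}

#' Render a synthetic post-implant CT from ground-truth contacts
#'
#' Each contact becomes an isotropic Gaussian density blob (peak
#' `amplitude`, standard deviation `sigma` mm) on a pseudo-random Gaussian
#' noise background; the same `seed` gives a bit-identical volume. The
#' affine is `diag(voxel_size)` with zero origin, so the field of view is
#' `shape * voxel_size` mm starting at the first voxel center (0,0,0).
#'
#' @param points n x 3 matrix of ground-truth contact world points (mm);
#'   every point must be at least `3 * sigma` inside the field of view.
#' @param shape Integer triple of voxel counts (default 96^3).
#' @param voxel_size Isotropic voxel edge in mm (default 0.5).
#' @param amplitude Blob peak intensity (default 1000).
#' @param sigma Blob standard deviation in mm (default 0.6).
#' @param noise_sd Background noise SD (default 20).
#' @param seed RNG seed for the noise (default 1).
#' @return A [ct_volume()].
#' @export
render_ct <- function(points, shape = c(96, 96, 96), voxel_size = 0.5,
                      amplitude = 1000, sigma = 0.6, noise_sd = 20,
                      seed = 1L) {
  points <- as_points(points)
  shape <- as.integer(shape)
  fov_lo <- rep(0, 3) - voxel_size / 2
  fov_hi <- (shape - 1) * voxel_size + voxel_size / 2
  margin <- 3 * sigma
  bad <- points[, 1] < fov_lo[1] + margin | points[, 1] > fov_hi[1] - margin |
         points[, 2] < fov_lo[2] + margin | points[, 2] > fov_hi[2] - margin |
         points[, 3] < fov_lo[3] + margin | points[, 3] > fov_hi[3] - margin
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "contact (%.1f, %.1f, %.1f) mm is within 3*sigma of the field-of-view edge",
      points[i, 1], points[i, 2], points[i, 3]), call. = FALSE)
  }
  dat <- array(0, dim = shape)
  if (noise_sd > 0) {
    dat[] <- with_local_seed(seed, stats::rnorm(prod(shape), 0, noise_sd))
  }
  win <- ceiling(4 * sigma / voxel_size)
  for (i in seq_len(nrow(points))) {
    vc <- points[i, ] / voxel_size          # continuous 0-based voxel
    lo <- pmax(floor(vc) - win, 0)
    hi <- pmin(ceiling(vc) + win, shape - 1)
    ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
    kk <- seq.int(lo[3], hi[3])
    gx <- exp(-((ii - vc[1]) * voxel_size)^2 / (2 * sigma^2))
    gy <- exp(-((jj - vc[2]) * voxel_size)^2 / (2 * sigma^2))
    gz <- exp(-((kk - vc[3]) * voxel_size)^2 / (2 * sigma^2))
    blob <- amplitude * (gx %o% gy %o% gz)
    dat[ii + 1, jj + 1, kk + 1] <- dat[ii + 1, jj + 1, kk + 1] + blob
  }
  aff <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  ct_volume(dat, aff)
}

# Run expr under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Shaft fixture: ground truth plus rendered CT
#'
#' Convenience wrapper pairing [make_trajectory()] and [render_ct()], with
#' the trajectory centered in the field of view.
#'
#' @inheritParams make_trajectory
#' @inheritParams render_ct
#' @return List of class `trajectory_fixture`: `truth` (n x 3 world mm),
#'   `volume` ([ct_volume()]), `params`.
#' @export
make_shaft_fixture <- function(n = 8, spacing = 3.5, curvature_radius = Inf,
                               direction = c(1, 0, 0),
                               plane_normal = c(0, 0, 1),
                               shape = c(96, 96, 96), voxel_size = 0.5,
                               amplitude = 1000, sigma = 0.6, noise_sd = 20,
                               seed = 1L) {
  fov <- shape * voxel_size
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  probe <- make_trajectory(c(0, 0, 0), d, n, spacing, curvature_radius,
                           plane_normal)
  ctr <- (apply(probe, 2, min) + apply(probe, 2, max)) / 2
  start <- fov / 2 - ctr
  truth <- make_trajectory(start, d, n, spacing, curvature_radius,
                           plane_normal)
  vol <- render_ct(truth, shape, voxel_size, amplitude, sigma, noise_sd,
                   seed)
  structure(list(truth = truth, volume = vol,
                 params = list(n = n, spacing = spacing,
                               curvature_radius = curvature_radius,
                               sigma = sigma, amplitude = amplitude,
                               noise_sd = noise_sd, seed = seed)),
            class = "trajectory_fixture")
}

#' Synthetic parcellation volume from geometric regions
#'
#' Builds an integer label volume from a list of region specifications, each
#' a list with `id`, `name`, and either `type = "halfspace"` (`normal`,
#' `offset`: world points with `normal . p > offset` belong to the region)
#' or `type = "box"` (`min`, `max` world corners, inclusive). Voxels claimed
#' by no region get id 0 ("unknown"); voxels claimed by more than one region
#' are an error.
#'
#' @param shape Integer voxel counts.
#' @param affine 4x4 voxel-to-world matrix.
#' @param regions List of region specs as above.
#' @return A [label_volume()] with a generated lookup table.
#' @export
make_label_volume <- function(shape, affine = diag(4), regions) {
  shape <- as.integer(shape)
  vox <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  world <- cbind(vox, 1) %*% t(as_affine(affine))
  world <- world[, 1:3, drop = FALSE]
  lab <- integer(nrow(vox))
  claimed <- logical(nrow(vox))
  lut <- tibble::tibble(id = 0L, name = "unknown")
  for (rg in regions) {
    inside <- switch(rg$type,
      halfspace = as.vector(world %*% as.numeric(rg$normal)) > rg$offset,
      box = world[, 1] >= rg$min[1] & world[, 1] <= rg$max[1] &
            world[, 2] >= rg$min[2] & world[, 2] <= rg$max[2] &
            world[, 3] >= rg$min[3] & world[, 3] <= rg$max[3],
      stop("unknown region type: ", rg$type, call. = FALSE)
    )
    if (any(claimed & inside)) {
      stop("region '", rg$name, "' overlaps a previous region", call. = FALSE)
    }
    lab[inside] <- as.integer(rg$id)
    claimed <- claimed | inside
    lut <- dplyr::bind_rows(lut, tibble::tibble(id = as.integer(rg$id),
                                                name = rg$name))
  }
  label_volume(array(lab, dim = shape), affine, lut)
}

#' Icosphere mesh (closed triangulated sphere)
#'
#' Subdivided icosahedron with all vertices projected onto the sphere;
#' subdivision 0 is the icosahedron itself (12 vertices, 20 faces); each
#' subdivision quadruples the face count.
#'
#' @param center Sphere center (mm).
#' @param radius Sphere radius (mm).
#' @param subdivisions Non-negative integer.
#' @return A closed [surface_mesh()].
#' @export
make_icosphere <- function(center = c(0, 0, 0), radius = 50,
                           subdivisions = 2) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      assign(key, idx, envir = mid_cache)
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  verts <- sweep(v * radius, 2, as.numeric(center), "+")
  surface_mesh(verts, f)
}

#' Subdural-grid fixture on a spherical cap
#'
#' Places a `rows x cols` grid of points on the cap of a (near-)spherical
#' mesh around its +z pole, spaced geodesically, then displaces them toward
#' the sphere center by `inward_offset` mm — emulating post-craniotomy brain
#' shift. The on-surface cap points are kept as ground-truth recovery
#' targets.
#'
#' @param rows,cols Grid dimensions.
#' @param spacing Geodesic spacing in mm.
#' @param mesh A (near-)spherical [surface_mesh()], e.g. [make_icosphere()].
#' @param inward_offset Inward displacement in mm (0 = on the surface).
#' @return List: `points` (displaced, rows*cols x 3, row-major),
#'   `surface_targets` (cap points on the sphere), `rows`, `cols`.
#' @export
make_grid_fixture <- function(rows, cols, spacing, mesh, inward_offset = 8) {
  center <- colMeans(mesh$vertices)
  radius <- mean(sqrt(rowSums(sweep(mesh$vertices, 2, center)^2)))
  ang <- spacing / radius
  if (max(rows, cols) * ang > pi / 2) {
    stop("grid larger than the spherical cap", call. = FALSE)
  }
  if (inward_offset >= radius) {
    stop("inward_offset must be smaller than the sphere radius",
         call. = FALSE)
  }
  pts <- matrix(NA_real_, rows * cols, 3)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    # exponential map at the +z pole: planar grid coords -> sphere
    u <- (j - (cols + 1) / 2) * ang
    w <- (i - (rows + 1) / 2) * ang
    rho <- sqrt(u^2 + w^2)
    dirv <- if (rho < 1e-12) c(0, 0, 1) else {
      c(sin(rho) * u / rho, sin(rho) * w / rho, cos(rho))
    }
    pts[(i - 1) * cols + j, ] <- center + radius * dirv
  }
  inner <- sweep(sweep(pts, 2, center) * (1 - inward_offset / radius),
                 2, center, "+")
  list(points = inner, surface_targets = pts, rows = rows, cols = cols)
}

#' Down-sample a volume by block averaging
#'
#' Averages `factor^3` voxel blocks, emulating acquisition (or resampling)
#' at a coarser resolution. This is a test instrument for demonstrating why
#' localization must run on the full-resolution CT: small contacts that are
#' clearly above threshold at native resolution are diluted below it after
#' down-sampling.
#'
#' @param vol A [ct_volume()].
#' @param factor Integer block edge (default 2, e.g. 0.5 mm -> 1 mm).
#' @return A [ct_volume()] with `floor(shape / factor)` voxels per axis and
#'   a correspondingly scaled affine.
#' @export
downsample_volume <- function(vol, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 2L)
  sh <- vol$shape %/% factor
  dat <- vol$data[seq_len(sh[1] * factor), seq_len(sh[2] * factor),
                  seq_len(sh[3] * factor), drop = FALSE]
  # block mean via successive axis folding
  dim(dat) <- c(factor, sh[1], factor, sh[2], factor, sh[3])
  out <- apply(dat, c(2, 4, 6), mean)
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  # new voxel 0 center = mean of the first block's corner voxel centers
  shift <- vol$affine[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  aff[1:3, 4] <- aff[1:3, 4] + as.vector(shift)
  ct_volume(out, aff)
}
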