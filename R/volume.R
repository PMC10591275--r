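#' CT volume container
#'
#' A `ct_volume` bundles a 3-D scalar array with a 4x4 voxel-to-world affine
#' (mm, RAS). Voxel indices are 0-based throughout the package; all public
#' coordinates are world millimetres in the subject's native RAS frame.
#'
#' @param data 3-D numeric array of intensities.
#' @param affine 4x4 voxel-to-world matrix (mm, RAS); must be invertible.
#' @return An object of class `ct_volume` with elements `data`, `affine`,
#'   `shape` (integer triple).
#' @export
ct_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimensions",
         call. = FALSE)
  }
  affine <- as_affine(affine)
  structure(
    list(data = data, affine = affine, shape = as.integer(dim(data))),
    class = "ct_volume"
  )
}

as_affine <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  m <- matrix(as.numeric(m), 4L, 4L)  # drop any header attributes
  det_m <- det(m[1:3, 1:3, drop = FALSE])
  if (!is.finite(det_m) || abs(det_m) < 1e-12) {
    stop("affine is not invertible (singular voxel-to-world matrix)",
         call. = FALSE)
  }
  m
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ",
      paste(signif(voxel_spacing(x), 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Voxel spacing of a volume
#'
#' Column norms of the affine's rotation/scale block, in mm.
#' @param vol A [ct_volume()].
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
voxel_spacing <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3, drop = FALSE]^2))
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file (`.nii` or `.nii.gz`) at full native
#' resolution; the voxel data are never resampled or down-sampled. The
#' voxel-to-world affine is taken from the header with sform preferred over
#' qform (falling back to the pixdim-scaled identity when both codes are 0).
#'
#' @param path Path to a NIfTI file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("volume file does not exist: ", path, call. = FALSE)
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) {
      stop("cannot read '", path, "' as NIfTI: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  aff <- tryCatch(
    as_affine(RNifti::xform(img, useQuaternionFirst = FALSE)),
    error = function(e) {
      stop("bad NIfTI header in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  dat <- as.array(img)
  dat <- array(as.numeric(dat), dim = dim(dat)[1:3])  # drop header attrs
  ct_volume(dat, aff)
}

#' Write a volume to NIfTI
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_spacing(vol)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Accept a length-3 vector or an n x 3 matrix/data.frame; return n x 3 matrix.
as_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y", "z")])
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a point needs 3 coordinates", call. = FALSE)
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  p <- unname(as.matrix(p))
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must be n x 3", call. = FALSE)
  p
}

#' Voxel-to-world and world-to-voxel coordinate transforms
#'
#' Exact affine maps between continuous 0-based voxel indices and world mm.
#' Both accept a single point (length-3 vector) or an n x 3 matrix and return
#' a matrix of the same row count.
#'
#' @param vol A [ct_volume()] or [label_volume()].
#' @param vox,p Length-3 vector or n x 3 matrix (voxel indices / world mm).
#' @return n x 3 numeric matrix.
#' @export
voxel_to_world <- function(vol, vox) {
  v <- as_points(vox)
  out <- cbind(v, 1) %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, p) {
  w <- as_points(p)
  out <- cbind(w, 1) %*% t(solve(vol$affine))
  out[, 1:3, drop = FALSE]
}

in_bounds_voxel <- function(vol, vox, margin = 0) {
  sh <- vol$shape
  vox[, 1] >= -0.5 + margin & vox[, 1] <= sh[1] - 0.5 - margin &
    vox[, 2] >= -0.5 + margin & vox[, 2] <= sh[2] - 0.5 - margin &
    vox[, 3] >= -0.5 + margin & vox[, 3] <= sh[3] - 0.5 - margin
}

#' Sample intensity at world coordinates
#'
#' @param vol A [ct_volume()].
#' @param p World point(s), length-3 vector or n x 3 matrix (mm).
#' @param mode `"trilinear"` (8-neighbour interpolation) or `"nearest"`.
#' @return Numeric vector of sampled intensities.
#' @export
sample_intensity <- function(vol, p, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  w <- as_points(p)
  v <- world_to_voxel(vol, w)
  ok <- in_bounds_voxel(vol, v)
  if (!all(ok)) {
    bad <- w[which(!ok)[1], ]
    stop(sprintf("world point (%.3f, %.3f, %.3f) mm is outside the volume",
                 bad[1], bad[2], bad[3]), call. = FALSE)
  }
  if (mode == "nearest") {
    idx <- round(v) + 1  # to 1-based array indices
    idx <- pmin(pmax(idx, 1), matrix(vol$shape, nrow(idx), 3, byrow = TRUE))
    return(vol$data[idx])
  }
  # trilinear
  v0 <- floor(v)
  f <- v - v0
  sh <- vol$shape
  acc <- numeric(nrow(v))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
           (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
           (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- cbind(v0[, 1] + dx, v0[, 2] + dy, v0[, 3] + dz) + 1
    idx <- pmin(pmax(idx, 1), matrix(sh, nrow(idx), 3, byrow = TRUE))
    acc <- acc + wgt * vol$data[idx]
  }
  acc
}
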