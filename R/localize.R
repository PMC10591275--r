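#' Resolve a threshold specification against a volume
#'
#' A threshold spec is either an absolute intensity (`threshold`) or a
#' percentile of the finite intensities (`percentile`, default 99.5). Metal
#' contacts are the brightest structures in a post-implant CT, so a high
#' percentile isolates them without Hounsfield calibration.
#'
#' @param vol A [ct_volume()].
#' @param threshold Absolute intensity cutoff, or `NULL` to use `percentile`.
#' @param percentile Percentile in (0, 100) of finite intensities.
#' @return The absolute threshold value (scalar).
#' @export
resolve_threshold <- function(vol, threshold = NULL, percentile = 99.5) {
  if (!is.null(threshold)) return(as.numeric(threshold))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  v <- vol$data[is.finite(vol$data)]
  thr <- stats::quantile(v, percentile / 100, names = FALSE, type = 7)
  if (thr >= max(v) || min(v) == max(v)) {
    stop("degenerate volume: no voxel exceeds the ",
         percentile, "th percentile (constant or near-constant intensities)",
         call. = FALSE)
  }
  thr
}

#' Threshold a CT volume into a metal-candidate mask
#'
#' @inheritParams resolve_threshold
#' @return Logical array (same shape as the volume): voxels strictly above
#'   the threshold.
#' @export
ct_threshold <- function(vol, threshold = NULL, percentile = 99.5) {
  thr <- resolve_threshold(vol, threshold, percentile)
  mask <- vol$data > thr
  if (!is.null(threshold) && !any(mask)) {
    # absolute spec on an empty field is legitimate; degenerate percentile
    # volumes are caught in resolve_threshold
    mask
  }
  mask
}

#' Detect contact-density clusters in a thresholded CT
#'
#' Labels 26-connected components of the mask and summarises each as a
#' density candidate: intensity-weighted centroid (world mm), peak intensity,
#' voxel count. Candidates are sorted by descending peak intensity.
#'
#' @param vol A [ct_volume()].
#' @param mask Logical array from [ct_threshold()] (same shape as `vol`).
#' @return A tibble with columns `x`, `y`, `z`, `peak_intensity`,
#'   `n_voxels`; zero rows for an empty mask.
#' @export
detect_clusters <- function(vol, mask) {
  if (!identical(dim(mask), dim(vol$data))) {
    stop("mask shape does not match the volume", call. = FALSE)
  }
  idx <- which(mask)
  empty <- tibble::tibble(x = double(), y = double(), z = double(),
                          peak_intensity = double(), n_voxels = integer())
  if (length(idx) == 0L) return(empty)
  comp <- label_components_26(idx, dim(mask))
  vox <- arrayInd(idx, dim(mask)) - 1  # 0-based
  inten <- vol$data[idx]
  world <- voxel_to_world(vol, vox)
  rows <- lapply(split(seq_along(idx), comp), function(i) {
    w <- inten[i]
    ctr <- colSums(world[i, , drop = FALSE] * w) / sum(w)
    tibble::tibble(x = ctr[1], y = ctr[2], z = ctr[3],
                   peak_intensity = max(w), n_voxels = length(i))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$peak_intensity))
}

# 26-connected component labeling over a sparse voxel set.
# idx: linear indices into an array of dimension `dims`. Returns an integer
# component id per element of idx. BFS over a hash of the sparse set; cost is
# O(27 * n_mask), independent of volume size.
label_components_26 <- function(idx, dims) {
  n <- length(idx)
  pos <- new.env(hash = TRUE, size = max(16L, 2L * n))
  keys <- as.character(idx)
  for (i in seq_len(n)) assign(keys[i], i, envir = pos)
  vox <- arrayInd(idx, dims)
  # 26-neighborhood offsets in linear-index space
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      vi <- vox[i, ]
      cand <- sweep(nb, 2, vi, "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
            cand[, 2] >= 1 & cand[, 2] <= dims[2] &
            cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + dims[1] * (cand[, 2] - 1) +
        dims[1] * dims[2] * (cand[, 3] - 1)
      for (l in as.character(lin)) {
        j <- pos[[l]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# Above-threshold voxels within `radius` mm of world point `center`.
# Returns list(world = n x 3, weight = intensity - threshold) or NULL.
voxels_near <- function(vol, center, radius, thr) {
  vc <- drop(world_to_voxel(vol, center))
  sp <- voxel_spacing(vol)
  half <- ceiling(radius / sp) + 1
  lo <- pmax(floor(vc - half), 0)
  hi <- pmin(ceiling(vc + half), vol$shape - 1)
  if (any(lo > hi)) return(NULL)
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  sub <- vol$data[ii + 1, jj + 1, kk + 1, drop = FALSE]
  keep <- which(sub > thr)
  if (length(keep) == 0L) return(NULL)
  vijk <- arrayInd(keep, dim(sub))
  vox <- cbind(ii[vijk[, 1]], jj[vijk[, 2]], kk[vijk[, 3]])
  world <- voxel_to_world(vol, vox)
  d2 <- rowSums(sweep(world, 2, as.numeric(center))^2)
  inr <- d2 <= radius^2
  if (!any(inr)) return(NULL)
  list(world = world[inr, , drop = FALSE],
       vox = vox[inr, , drop = FALSE],
       intensity = sub[keep][inr],
       weight = sub[keep][inr] - thr,
       dist = sqrt(d2[inr]))
}

#' Refine a contact coordinate to the intensity-weighted CT center
#'
#' Starting from a seed (e.g. a user click or a geometric prediction), takes
#' the intensity-weighted centroid of above-threshold voxels within `radius`
#' of the current estimate and iterates until the estimate moves less than
#' 0.01 mm or 10 iterations. Weights are the intensity excess above the
#' threshold (clipped at zero) so background never biases the centroid.
#'
#' @param vol A [ct_volume()].
#' @param seed World point (mm): length-3 vector.
#' @param radius Refinement radius in mm (default 2.0).
#' @inheritParams resolve_threshold
#' @return Length-3 numeric: the converged world coordinate (mm).
#' @export
refine_contact <- function(vol, seed, radius = 2.0, threshold = NULL,
                           percentile = 99.5) {
  stopifnot(radius > 0)
  thr <- resolve_threshold(vol, threshold, percentile)
  est <- as.numeric(seed)
  for (it in seq_len(10L)) {
    nb <- voxels_near(vol, est, radius, thr)
    if (is.null(nb)) {
      stop(sprintf(
        "NoDensity: no above-threshold CT voxel within %.2f mm of (%.2f, %.2f, %.2f)",
        radius, est[1], est[2], est[3]), call. = FALSE)
    }
    new_est <- colSums(nb$world * nb$weight) / sum(nb$weight)
    moved <- sqrt(sum((new_est - est)^2))
    est <- new_est
    if (moved < 0.01) break
  }
  est
}
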