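# Shared in-code fixtures; everything is generated, nothing read from disk.

# Small noise-free volume with one Gaussian blob at `center` (world mm).
blob_volume <- function(center = c(8, 8, 8), sigma = 0.6, amplitude = 1000,
                        shape = c(32, 32, 32), voxel_size = 0.5,
                        noise_sd = 0, seed = 1L) {
  render_ct(matrix(center, 1), shape = shape, voxel_size = voxel_size,
            amplitude = amplitude, sigma = sigma, noise_sd = noise_sd,
            seed = seed)
}

# Brute-force intensity-weighted centroid of all above-threshold voxels
# within `radius` of `center` — plain loops, independent of the package's
# refinement path.
brute_centroid <- function(vol, center, radius, thr) {
  acc <- c(0, 0, 0); wsum <- 0
  sh <- vol$shape
  for (i in 0:(sh[1] - 1)) for (j in 0:(sh[2] - 1)) for (k in 0:(sh[3] - 1)) {
    val <- vol$data[i + 1, j + 1, k + 1]
    if (val <= thr) next
    w <- drop(voxel_to_world(vol, c(i, j, k)))
    if (sum((w - center)^2) > radius^2) next
    acc <- acc + (val - thr) * w
    wsum <- wsum + (val - thr)
  }
  acc / wsum
}

# Independent nearest-point-on-triangle oracle: enumerate the face-plane
# projection (if its barycentrics are admissible), the three edge-segment
# projections and the three vertices, and take the closest candidate.
oracle_project <- function(mesh, p) {
  best <- NULL; bestd <- Inf
  seg_closest <- function(a, b, p) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    a + t * ab
  }
  for (f in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[f, 1], ]
    b <- mesh$vertices[mesh$faces[f, 2], ]
    c <- mesh$vertices[mesh$faces[f, 3], ]
    cands <- list(a, b, c,
                  seg_closest(a, b, p), seg_closest(b, c, p),
                  seg_closest(c, a, p))
    ab <- b - a; ac <- c - a
    n <- c(ab[2] * ac[3] - ab[3] * ac[2],
           ab[3] * ac[1] - ab[1] * ac[3],
           ab[1] * ac[2] - ab[2] * ac[1])
    n <- n / sqrt(sum(n^2))
    q <- p - sum((p - a) * n) * n
    # barycentric admissibility of the in-plane projection
    m <- cbind(b - a, c - a)
    st <- tryCatch(qr.solve(m, q - a), error = function(e) c(-1, -1))
    if (all(st >= 0) && sum(st) <= 1) cands <- c(cands, list(q))
    for (cand in cands) {
      d <- sum((cand - p)^2)
      if (d < bestd) { bestd <- d; best <- cand }
    }
  }
  best
}

# Brute-force 3x3x3 majority vote with the center-voxel tie rule.
oracle_vote <- function(lv, p) {
  ctr <- round(drop(world_to_voxel(lv, p)))
  sh <- lv$shape
  labs <- integer(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    v <- ctr + c(di, dj, dk)
    if (any(v < 0) || any(v >= sh)) next
    labs <- c(labs, lv$labels[v[1] + 1, v[2] + 1, v[3] + 1])
  }
  counts <- table(labs)
  top <- names(counts[counts == max(counts)])
  if (length(top) > 1L) {
    return(lv$labels[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1])
  }
  as.integer(top)
}

expect_points_close <- function(actual, expected, tol) {
  d <- sqrt(rowSums((as_matrix3(actual) - as_matrix3(expected))^2))
  expect_lt(max(d), tol)
}

as_matrix3 <- function(x) {
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  if (is.null(dim(x))) return(matrix(x, ncol = 3))
  x
}
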