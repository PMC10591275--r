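cfg_abs <- snap_config(threshold = 100)

test_that("snapping picks the displaced blob and honors the exclusion rule", {
  vol <- render_ct(matrix(c(8, 8, 8), 1), shape = c(32, 32, 32),
                   voxel_size = 0.5, noise_sd = 0)
  predicted <- c(8, 8, 8) + c(0.9, -0.6, 0.4)  # 1.15 mm off
  got <- snap_to_density(vol, predicted, cfg_abs)
  expect_lt(sqrt(sum((got - c(8, 8, 8))^2)), 0.05)

  # the only density within reach lies 0.5 mm from a used contact
  # (every above-threshold voxel is inside the 1.5 mm exclusion zone)
  used <- matrix(c(8.5, 8, 8), 1)
  expect_error(
    snap_to_density(vol, predicted, snap_config(threshold = 300),
                    used = used),
    "SnapFailure")
})

test_that("equal-peak tie breaks to the candidate nearer the prediction", {
  dat <- array(0, dim = c(40, 20, 20))
  dat[17, 9, 9] <- 500   # 0-based (16,8,8): world x = 8.0, 0.6 mm away
  dat[22, 9, 9] <- 500   # 0-based (21,8,8): world x = 10.5, 1.9 mm away
  vol <- ct_volume(dat, diag(c(0.5, 0.5, 0.5, 1)))
  predicted <- c(8.6, 4.0, 4.0)
  # exhaustive oracle over admissible candidate voxels
  cand <- which(dat > 100, arr.ind = TRUE) - 1
  w <- voxel_to_world(vol, cand)
  d <- sqrt(rowSums(sweep(w, 2, predicted)^2))
  admissible <- w[d < 2, , drop = FALSE]
  oracle <- admissible[which.min(d[d < 2]), ]
  got <- snap_to_density(vol, predicted, cfg_abs)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("straight shafts are recovered end to end by extrapolation", {
  fix <- make_shaft_fixture(n = 8, spacing = 3.5, seed = 31)
  res <- extrapolate_shaft(fix$volume, fix$truth[1, ] + c(0.3, -0.2, 0.2),
                           fix$truth[2, ] + c(-0.1, 0.3, -0.2), 8)
  expect_equal(nrow(res), 8L)
  err <- sqrt(rowSums((as.matrix(res[, c("x", "y", "z")]) - fix$truth)^2))
  expect_lt(max(err), 0.2)
  expect_true(all(res$provenance %in% c("refined", "extrapolated")))
  # n_total = 2 returns just the refined seeds
  two <- extrapolate_shaft(fix$volume, fix$truth[1, ], fix$truth[2, ], 2)
  expect_equal(nrow(two), 2L)
  expect_equal(two$provenance, c("refined", "refined"))
})

test_that("gently arced shafts are recovered by extrapolation", {
  fix <- make_shaft_fixture(n = 12, spacing = 3.5, curvature_radius = 80,
                            seed = 32)
  res <- extrapolate_shaft(fix$volume, fix$truth[1, ], fix$truth[2, ], 12)
  err <- sqrt(rowSums((as.matrix(res[, c("x", "y", "z")]) - fix$truth)^2))
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("interpolation recovers straight and sharply bent strips", {
  fix <- make_shaft_fixture(n = 10, spacing = 3.5, seed = 33)
  res <- interpolate_shaft(fix$volume, fix$truth[1, ] + c(0.2, 0.2, -0.3),
                           fix$truth[10, ] + c(-0.3, 0.1, 0.2), 10)
  err <- sqrt(rowSums((as.matrix(res[, c("x", "y", "z")]) - fix$truth)^2))
  expect_lt(max(err), 0.2)

  # occipital-pole-like strip: 90 degrees of turn over 8 contacts
  r90 <- 7 * 3.5 / (pi / 2)
  arc <- make_shaft_fixture(n = 8, spacing = 3.5, curvature_radius = r90,
                            seed = 34)
  res2 <- interpolate_shaft(arc$volume, arc$truth[1, ], arc$truth[8, ], 8)
  err2 <- sqrt(rowSums((as.matrix(res2[, c("x", "y", "z")]) - arc$truth)^2))
  expect_lt(sqrt(mean(err2^2)), 0.7)
  expect_equal(nrow(res2), 8L)

  # n_total = 2 returns the refined endpoints
  two <- interpolate_shaft(fix$volume, fix$truth[1, ], fix$truth[10, ], 2)
  expect_equal(nrow(two), 2L)
})

test_that("straight-shaft interpolation agrees with refined geometric spacing", {
  fix <- make_shaft_fixture(n = 9, spacing = 3.5, seed = 35)
  res <- interpolate_shaft(fix$volume, fix$truth[1, ], fix$truth[9, ], 9)
  geo <- geometric_interpolate(fix$truth[1, ], fix$truth[9, ], 9)
  refined_geo <- t(apply(as.matrix(geo[, c("x", "y", "z")]), 1, function(p) {
    refine_contact(fix$volume, p, radius = 2)
  }))
  expect_points_close(res, refined_geo, 0.2)
})

test_that("geometric interpolation is exact arithmetic", {
  res <- geometric_interpolate(c(0, 0, 0), c(0, 0, 9), 4)
  expect_equal(res$z, c(0, 3, 6, 9))
  expect_equal(res$x, rep(0, 4))
  two <- geometric_interpolate(c(1, 2, 3), c(4, 5, 6), 2)
  expect_equal(as.matrix(two[, c("x", "y", "z")]),
               rbind(c(1, 2, 3), c(4, 5, 6)), ignore_attr = TRUE)
  set.seed(36)
  a <- rnorm(3); b <- rnorm(3); n <- 7
  res3 <- geometric_interpolate(a, b, n)
  steps <- diff(as.matrix(res3[, c("x", "y", "z")]))
  expect_equal(sqrt(rowSums(steps^2)),
               rep(sqrt(sum((b - a)^2)) / (n - 1), n - 1), tolerance = 1e-12)
})

test_that("random shafts: full recovery, no duplicates, correct counts", {
  set.seed(37)
  n_fix <- 12
  for (i in seq_len(n_fix)) {
    curvature <- if (i %% 2 == 0) Inf else runif(1, 60, 200)
    n <- sample(6:12, 1)
    fix <- make_shaft_fixture(n = n, spacing = 3.5,
                              curvature_radius = curvature,
                              direction = rnorm(3), plane_normal = rnorm(3),
                              noise_sd = runif(1, 0, 100), seed = 100 + i)
    res <- extrapolate_shaft(fix$volume, fix$truth[1, ], fix$truth[2, ], n)
    expect_equal(nrow(res), n)
    pts <- as.matrix(res[, c("x", "y", "z")])
    err <- sqrt(rowSums((pts - fix$truth)^2))
    expect_lt(mean(err), 0.5)
    # duplicate-selection guard: pairwise distances exceed the exclusion radius
    expect_gt(min(dist(pts)), snap_config()$exclusion_radius)
  }
})
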