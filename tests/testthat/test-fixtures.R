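test_that("straight trajectories have exact spacing and direction", {
  pts <- make_trajectory(c(0, 0, 0), c(0, 0, 1), 3, 3)
  expect_equal(pts[, 3], c(0, 3, 6))
  expect_equal(pts[, 1], rep(0, 3))
  two <- make_trajectory(c(1, 1, 1), c(1, 0, 0), 2, 5)
  expect_equal(sqrt(sum((two[2, ] - two[1, ])^2)), 5)
  expect_error(make_trajectory(c(0, 0, 0), c(0, 0, 0), 3, 3), "nonzero")
})

test_that("arc trajectories obey circle geometry", {
  r <- 40; spacing <- 3.5; n <- 10
  pts <- make_trajectory(c(0, 0, 0), c(1, 0, 0), n, spacing,
                         curvature_radius = r, plane_normal = c(0, 0, 1))
  # chord length for arc length s on a circle of radius r: 2 r sin(s / 2r)
  chords <- sqrt(rowSums(diff(pts)^2))
  expect_equal(chords, rep(2 * r * sin(spacing / (2 * r)), n - 1),
               tolerance = 1e-9)
  # constant turning angle spacing / r between successive chords
  steps <- diff(pts)
  cosines <- vapply(seq_len(n - 2), function(i) {
    sum(steps[i, ] * steps[i + 1, ]) /
      (sqrt(sum(steps[i, ]^2)) * sqrt(sum(steps[i + 1, ]^2)))
  }, numeric(1))
  expect_equal(cosines, rep(cos(spacing / r), n - 2), tolerance = 1e-9)
  # the arc stays in the plane z = 0
  expect_lt(max(abs(pts[, 3])), 1e-9)
  # first point and initial tangent are honored
  expect_equal(pts[1, ], c(0, 0, 0), tolerance = 1e-12)
})

test_that("rendered blobs sit at their ground-truth centroids", {
  pts <- matrix(c(8, 8, 8), 1)
  vol <- render_ct(pts, shape = c(32, 32, 32), voxel_size = 0.5,
                   noise_sd = 0)
  ctr <- brute_centroid(vol, c(8, 8, 8), radius = 2.5, thr = 50)
  expect_lt(sqrt(sum((ctr - c(8, 8, 8))^2)), 0.05)
  # same seed, bit-identical; amplitude 0 leaves pure noise
  v1 <- render_ct(pts, shape = c(16, 16, 16), voxel_size = 1,
                  noise_sd = 20, seed = 7)
  v2 <- render_ct(pts, shape = c(16, 16, 16), voxel_size = 1,
                  noise_sd = 20, seed = 7)
  expect_identical(v1$data, v2$data)
  # amplitude 0 gives the bare noise field: the difference to v1 is the
  # nonnegative blob with the requested peak
  v3 <- render_ct(pts, shape = c(16, 16, 16), voxel_size = 1,
                  amplitude = 0, noise_sd = 20, seed = 7)
  blob <- v1$data - v3$data
  expect_gte(min(blob), 0)
  expect_equal(max(blob), 1000, tolerance = 1e-6)
  expect_error(render_ct(matrix(c(0.5, 8, 8), 1), shape = c(32, 32, 32),
                         voxel_size = 0.5), "edge")
})

test_that("fixture generation does not disturb the session RNG", {
  set.seed(77)
  before <- .Random.seed
  invisible(render_ct(matrix(c(8, 8, 8), 1), shape = c(16, 16, 16),
                      voxel_size = 1, noise_sd = 10, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("label volumes realize their geometric spec exactly", {
  lv <- make_label_volume(
    shape = c(10, 10, 10), affine = diag(4),
    regions = list(list(id = 3L, name = "upper", type = "halfspace",
                        normal = c(0, 0, 1), offset = 4.5)))
  expect_equal(sum(lv$labels == 3L), 10 * 10 * 5)  # z in 5..9
  expect_equal(lv$labels[1, 1, 5], 0L)
  expect_equal(lv$labels[1, 1, 6], 3L)
  expect_equal(lut_names <- lv$lut$name, c("unknown", "upper"))

  expect_error(make_label_volume(
    shape = c(6, 6, 6), affine = diag(4),
    regions = list(
      list(id = 1L, name = "a", type = "box", min = c(0, 0, 0),
           max = c(3, 3, 3)),
      list(id = 2L, name = "b", type = "box", min = c(2, 2, 2),
           max = c(5, 5, 5)))), "overlap")
})

test_that("icospheres are closed with all vertices on the sphere", {
  ico <- make_icosphere(radius = 10, subdivisions = 0)
  expect_equal(nrow(ico$vertices), 12L)
  expect_equal(nrow(ico$faces), 20L)
  expect_true(is_closed(ico))
  s2 <- make_icosphere(center = c(1, 2, 3), radius = 7, subdivisions = 2)
  expect_equal(nrow(s2$faces), 20L * 16L)
  expect_true(is_closed(s2))
  radii <- sqrt(rowSums(sweep(s2$vertices, 2, c(1, 2, 3))^2))
  expect_lt(max(abs(radii - 7)), 1e-9)
})

test_that("grid fixtures start on the cap and move inside with offset", {
  mesh <- make_icosphere(radius = 50, subdivisions = 2)
  on_surf <- make_grid_fixture(2, 4, 10, mesh, inward_offset = 0)
  expect_equal(nrow(on_surf$points), 8L)
  radii <- sqrt(rowSums(on_surf$points^2))
  expect_lt(max(abs(radii - 50)), 1e-9)

  inside <- make_grid_fixture(2, 4, 10, mesh, inward_offset = 8)
  expect_true(all(is_inside(mesh, inside$points)))
  expect_equal(inside$surface_targets, on_surf$points)
  expect_error(make_grid_fixture(10, 10, 40, mesh), "cap")
})

test_that("block-mean down-sampling halves resolution and recenters voxels", {
  fix <- make_shaft_fixture(n = 4, spacing = 3.5, shape = c(64, 64, 64),
                            seed = 8)
  lo <- downsample_volume(fix$volume, 2)
  expect_equal(lo$shape, c(32L, 32L, 32L))
  expect_equal(voxel_spacing(lo), rep(1, 3))
  # mean intensity is preserved by block averaging
  expect_equal(mean(lo$data), mean(fix$volume$data), tolerance = 1e-12)
  # voxel (0,0,0) of the coarse grid sits at the mean of the fine block
  corner_fine <- voxel_to_world(fix$volume, rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(drop(voxel_to_world(lo, c(0, 0, 0))), colMeans(corner_fine))
})

test_that("small contacts vanish when the CT is down-sampled (full-resolution principle)", {
  big <- rbind(c(10, 16, 16), c(22, 16, 16))
  small <- rbind(c(14, 12.25, 16.25), c(18, 20.25, 15.75))
  vol <- render_ct(big, shape = c(64, 64, 64), voxel_size = 0.5,
                   noise_sd = 0)
  vol2 <- render_ct(small, shape = c(64, 64, 64), voxel_size = 0.5,
                    amplitude = 600, sigma = 0.25, noise_sd = 0)
  vol$data <- vol$data + vol2$data
  native <- detect_clusters(vol, ct_threshold(vol, threshold = 150))
  coarse_vol <- downsample_volume(vol, 2)
  coarse <- detect_clusters(coarse_vol,
                            ct_threshold(coarse_vol, threshold = 150))
  expect_equal(nrow(native), 4L)
  expect_lt(nrow(coarse), nrow(native))
  expect_equal(nrow(coarse), 2L)  # only the standard contacts survive
})
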