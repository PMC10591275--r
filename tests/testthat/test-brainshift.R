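sphere <- make_icosphere(center = c(0, 0, 0), radius = 50, subdivisions = 2)

test_that("winding-number containment matches analytic sphere geometry", {
  expect_true(is_inside(sphere, c(0, 0, 0)))
  expect_false(is_inside(sphere, c(100, 0, 0)))
  # just under the surface of the circumscribed sphere: use a vertex
  # direction so the mesh locally reaches the full radius
  vdir <- sphere$vertices[1, ] / 50
  expect_true(is_inside(sphere, vdir * 49.9))
  expect_false(is_inside(sphere, vdir * 50.1))
  # open mesh is rejected
  open_mesh <- surface_mesh(sphere$vertices, sphere$faces[-1, ])
  expect_false(is_closed(open_mesh))
  expect_error(is_inside(open_mesh, c(0, 0, 0)), "closed")
})

test_that("projection returns the exact nearest surface point", {
  # a point already on a face projects to itself
  f1 <- sphere$faces[1, ]
  on_face <- colMeans(sphere$vertices[f1, ])
  proj <- drop(project_to_surface(sphere, on_face))
  expect_lt(sqrt(sum((proj - on_face)^2)), 1e-9)

  # interior point along +x: lands within one edge length of (50,0,0)
  edge_len <- sqrt(sum((sphere$vertices[sphere$faces[1, 1], ] -
                          sphere$vertices[sphere$faces[1, 2], ])^2))
  p <- drop(project_to_surface(sphere, c(45, 0, 0)))
  expect_lt(sqrt(sum((p - c(50, 0, 0))^2)), edge_len)

  expect_error(project_to_surface(surface_mesh(sphere$vertices,
                                               matrix(integer(), 0, 3)),
                                  c(0, 0, 0)), "faces")
})

test_that("projection matches the exhaustive per-face oracle", {
  coarse <- make_icosphere(radius = 30, subdivisions = 1)
  set.seed(51)
  pts <- matrix(rnorm(3 * 60, sd = 25), ncol = 3)
  got <- project_to_surface(coarse, pts)
  for (i in seq_len(nrow(pts))) {
    want <- oracle_project(coarse, pts[i, ])
    expect_lt(sqrt(sum((got[i, ] - want)^2)), 1e-8)
  }
})

grid_table <- function(fix, plan) {
  tab <- table_from_plan(plan)
  tab$x <- fix$points[, 1]
  tab$y <- fix$points[, 2]
  tab$z <- fix$points[, 3]
  tab$provenance <- "refined"
  tab
}

test_that("interior ECoG grid contacts land on the mesh with topology kept", {
  plan <- electrode_plan(contact_group("GR", "ECoG-grid", 8,
                                       grid_dims = c(2, 4), spacing = 10))
  fix <- make_grid_fixture(2, 4, 10, sphere, inward_offset = 8)
  tab <- grid_table(fix, plan)
  out <- correct_brain_shift(tab, plan, sphere, lambda_topo = 1)
  sh <- as.matrix(out[, c("x_shifted", "y_shifted", "z_shifted")])
  expect_true(all(!is.na(sh)))
  # on the mesh
  d <- sqrt(rowSums((project_to_surface(sphere, sh) - sh)^2))
  expect_lt(max(d), 1e-3)
  # native coordinates retained
  expect_equal(out$x, fix$points[, 1])
  # adjacent-pair distances within 25% of the originals
  adj <- rbind(cbind(1:3, 2:4), cbind(5:7, 6:8), cbind(1:4, 5:8))
  d0 <- sqrt(rowSums((fix$points[adj[, 1], ] - fix$points[adj[, 2], ])^2))
  d1 <- sqrt(rowSums((sh[adj[, 1], ] - sh[adj[, 2], ])^2))
  expect_true(all(abs(d1 - d0) / d0 < 0.25))
})

test_that("sEEG contacts are bit-identical and surface contacts untouched", {
  plan <- electrode_plan(
    contact_group("LA", "sEEG", 4, spacing = 3.5),
    contact_group("ST", "ECoG-strip", 4, spacing = 10))
  tab <- table_from_plan(plan)
  # sEEG shaft deep inside the sphere
  tab$x[1:4] <- seq(0, 10.5, by = 3.5); tab$y[1:4] <- 0; tab$z[1:4] <- 0
  # strip: two contacts outside, two inside
  strip <- rbind(c(0, 0, 60), c(10, 0, 58), c(0, 20, 40), c(10, 18, 38))
  tab$x[5:8] <- strip[, 1]; tab$y[5:8] <- strip[, 2]; tab$z[5:8] <- strip[, 3]
  out <- correct_brain_shift(tab, plan, sphere)
  expect_identical(out$x[1:4], tab$x[1:4])
  expect_identical(out$y[1:4], tab$y[1:4])
  expect_identical(out$z[1:4], tab$z[1:4])
  expect_true(all(is.na(out$x_shifted[1:4])))
  outside <- !is_inside(sphere, strip)
  expect_true(all(is.na(out$x_shifted[5:8][outside])))
  expect_true(all(!is.na(out$x_shifted[5:8][!outside])))
})

test_that("a single interior strip contact with lambda 0 is pure projection", {
  plan <- electrode_plan(contact_group("S1", "ECoG-strip", 1))
  tab <- table_from_plan(plan)
  tab$x[1] <- 30; tab$y[1] <- 5; tab$z[1] <- -4
  out <- correct_brain_shift(tab, plan, sphere, lambda_topo = 0)
  want <- drop(project_to_surface(sphere, c(30, 5, -4)))
  got <- c(out$x_shifted[1], out$y_shifted[1], out$z_shifted[1])
  expect_lt(sqrt(sum((got - want)^2)), 1e-9)
})

test_that("raising lambda_topo never worsens the topology term", {
  plan <- electrode_plan(contact_group("GR", "ECoG-grid", 8,
                                       grid_dims = c(2, 4), spacing = 10))
  fix <- make_grid_fixture(2, 4, 10, sphere, inward_offset = 8)
  tab <- grid_table(fix, plan)
  adj <- rbind(cbind(1:3, 2:4), cbind(5:7, 6:8), cbind(1:4, 5:8))
  d0 <- sqrt(rowSums((fix$points[adj[, 1], ] - fix$points[adj[, 2], ])^2))
  topo_term <- function(lambda) {
    out <- correct_brain_shift(tab, plan, sphere, lambda_topo = lambda)
    sh <- as.matrix(out[, c("x_shifted", "y_shifted", "z_shifted")])
    d1 <- sqrt(rowSums((sh[adj[, 1], ] - sh[adj[, 2], ])^2))
    sum((d1 - d0)^2)
  }
  terms <- vapply(c(0, 0.5, 2, 8), topo_term, numeric(1))
  expect_true(all(diff(terms) <= 1e-6))
})

test_that("all-outside tables pass through unchanged", {
  plan <- electrode_plan(contact_group("ST", "ECoG-strip", 3))
  tab <- table_from_plan(plan)
  tab$x <- c(60, 65, 70); tab$y <- 0; tab$z <- 0
  out <- correct_brain_shift(tab, plan, sphere)
  expect_true(all(is.na(out$x_shifted)))
  expect_equal(out$x, tab$x)
})

test_that("surface meshes round-trip through GIfTI and FreeSurfer formats", {
  mesh <- make_icosphere(radius = 25, subdivisions = 1)
  gii <- tempfile(fileext = ".surf.gii")
  write_surface(mesh, gii)
  back <- read_surface(gii)
  expect_equal(back$faces, mesh$faces)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-4)  # float32

  fs <- tempfile(fileext = "")
  write_surface(mesh, fs)
  back2 <- read_surface(fs)
  expect_equal(back2$faces, mesh$faces)
  expect_lt(max(abs(back2$vertices - mesh$vertices)), 1e-4)
  expect_true(is_closed(back2))
})
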