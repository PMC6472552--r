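test_that("mean nearest-vertex distance matches the brute-force oracle", {
  s <- sphere_mesh(r = 10, subdivisions = 1)
  expect_equal(mean_nearest_vertex_distance(s, s), 0)

  a <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)))
  b <- triangle_mesh(rbind(c(3, 4, 0), c(10, 10, 0), c(3, 5, 0)),
                     rbind(c(1, 2, 3)))
  expect_equal(cpp_dist <- pneumosim:::cpp_nn_dist(a$vertices[1, , drop = FALSE],
                                                   b$vertices[1, , drop = FALSE]),
               5)

  set.seed(13)
  va <- matrix(rnorm(300), 100, 3)
  vb <- matrix(rnorm(600), 200, 3)
  ma <- triangle_mesh(va, rbind(c(1, 2, 3)))
  mb <- triangle_mesh(vb, rbind(c(1, 2, 3)))
  brute <- mean(apply(va, 1, function(p)
    min(sqrt(colSums((t(vb) - p)^2)))))
  expect_identical(mean_nearest_vertex_distance(ma, mb), brute)
  # symmetric variant averages both directions
  brute_ba <- apply(vb, 1, function(p) min(sqrt(colSums((t(va) - p)^2))))
  expect_equal(mean_nearest_vertex_distance(ma, mb, symmetric = TRUE),
               (brute * 100 + sum(brute_ba)) / 300)
})

test_that("voxel non-overlap error enumerates the stated conventions", {
  g <- function(occ) voxel_grid(c(0, 0, 0), 1, c(2, 2, 1), occ)
  a <- g(c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(voxel_overlap_error(a, a), list(count = 0L, percent = 0))

  b <- g(c(FALSE, FALSE, TRUE, TRUE))
  e <- voxel_overlap_error(a, b)
  expect_identical(e$count, 4L)
  expect_equal(e$percent, 100)

  a2 <- g(c(TRUE, TRUE, FALSE, FALSE))
  b1 <- g(c(TRUE, FALSE, FALSE, FALSE))
  e <- voxel_overlap_error(a2, b1)
  expect_identical(e$count, 1L)
  expect_equal(e$percent, 100 / 3)
  # symmetry in the arguments
  e2 <- voxel_overlap_error(b1, a2)
  expect_identical(e, e2)

  mis <- voxel_grid(c(0, 0, 0), 2, c(2, 2, 1), rep(TRUE, 4))
  expect_error(voxel_overlap_error(a, mis), "spacing")
  offgrid <- voxel_grid(c(0.31, 0, 0), 1, c(2, 2, 1), rep(TRUE, 4))
  expect_error(voxel_overlap_error(a, offgrid), "lattice")
})

test_that("voxel error of two aligned voxelised spheres behaves sanely", {
  a <- voxelize(sphere_mesh(r = 8, subdivisions = 3), 1)
  b <- voxelize(sphere_mesh(r = 8, subdivisions = 3, center = c(3, 0, 0)), 1)
  e <- voxel_overlap_error(a, b)
  expect_gt(e$percent, 0)
  expect_lt(e$percent, 100)
  expect_true(e$count %% 1 == 0)
})

test_that("Hausdorff distance reproduces analytic sphere cases", {
  s <- sphere_mesh(r = 50, subdivisions = 3)
  self <- hausdorff_distance(s, s, samples_per_area = 0.25)
  expect_equal(self$mean, 0)
  expect_equal(self$max, 0)

  moved <- s
  moved$vertices <- sweep(s$vertices, 2, c(0, 0, 10), `+`)
  rep_ <- hausdorff_distance(s, moved, samples_per_area = 0.25)
  expect_equal(rep_$max, 10, tolerance = 0.02)

  bigger <- sphere_mesh(r = 52, subdivisions = 3)
  rep2 <- hausdorff_distance(s, bigger, samples_per_area = 0.25)
  expect_equal(rep2$mean, 2, tolerance = 0.02)
  expect_equal(rep2$max, 2, tolerance = 0.02)
  # symmetric max dominates both directed maxima by construction
  expect_gte(rep2$max + 1e-12, max(rep2$distances$a_to_b))
  expect_gte(rep2$max + 1e-12, max(rep2$distances$b_to_a))

  degenerate <- triangle_mesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                              rbind(c(1, 2, 3)))
  expect_error(hausdorff_distance(degenerate, s), "zero-area")
})

test_that("geodesic distances match planar and great-circle closed forms", {
  g <- grid_mesh(11)   # unit-spaced flat grid
  # two ends of one row: straight path along collinear edges
  expect_equal(geodesic_distance(g, 1, 11), 10, tolerance = 1e-9)
  expect_equal(geodesic_distance(g, 5, 5), 0)

  s <- sphere_mesh(r = 100, subdivisions = 3)
  v1 <- which.max(s$vertices[, 3])
  v2 <- which.min(s$vertices[, 3])
  d <- geodesic_distance(s, v1, v2)
  expect_lt(abs(d - pi * 100) / (pi * 100), 0.02)

  two <- triangle_mesh(rbind(diag(3), diag(3) + 10),
                       rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(geodesic_distance(two, 1, 4), "disconnected")
})

test_that("landmark distances follow phantom symmetry and stretch under inflation", {
  ph <- make_phantom(reduced_phantom_spec(resolution = 3))
  lm <- make_landmarked_wall(ph)
  d <- landmark_distances(ph$wall, lm)
  expect_lt(abs(d[["U_ASIS_R"]] - d[["U_ASIS_L"]]) / d[["U_ASIS_R"]], 0.01)
  expect_gt(d[["XS_PS"]], d[["U_ASIS_R"]])

  same <- compare_landmark_distances(ph$wall, ph$wall, lm)
  expect_equal(same$delta, rep(0, 3))

  ref <- make_inflated_reference(ph, 12)
  tab <- compare_landmark_distances(ph$wall, ref$wall, lm)
  expect_true(all(tab$delta >= 0))

  bad <- lm
  names(bad)[1] <- "NOPE"
  expect_error(landmark_distances(ph$wall, bad), "XS")
})

test_that("metrics scale linearly and are translation invariant", {
  a <- sphere_mesh(r = 20, subdivisions = 2)
  b <- sphere_mesh(r = 23, subdivisions = 2, center = c(2, 1, 0))
  s <- 0.5
  as <- scale_mesh(a, s)
  bs <- scale_mesh(b, s)
  expect_equal(mean_nearest_vertex_distance(as, bs),
               s * mean_nearest_vertex_distance(a, b), tolerance = 1e-12)
  v1 <- 5; v2 <- 150
  expect_equal(geodesic_distance(as, v1, v2),
               s * geodesic_distance(a, v1, v2), tolerance = 1e-9)
  h <- hausdorff_distance(a, b, samples_per_area = 1)
  hs <- hausdorff_distance(as, bs, samples_per_area = 1 / s^2)
  expect_equal(hs$max, s * h$max, tolerance = 1e-6)
  expect_equal(hs$mean, s * h$mean, tolerance = 1e-6)

  t <- c(13, -4, 7)
  at <- a; at$vertices <- sweep(a$vertices, 2, t, `+`)
  bt <- b; bt$vertices <- sweep(b$vertices, 2, t, `+`)
  expect_equal(mean_nearest_vertex_distance(at, bt),
               mean_nearest_vertex_distance(a, b), tolerance = 1e-9)
  expect_equal(hausdorff_distance(at, bt, 1)$max, h$max, tolerance = 1e-9)
})
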