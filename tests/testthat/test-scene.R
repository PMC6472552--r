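test_that("soft-body sampling respects Poisson-disc spacing and is deterministic", {
  s <- sphere_mesh(r = 50, subdivisions = 3)
  sb <- build_soft_body(s, radius = 2.7, seed = 3)
  nn <- pneumosim:::cpp_knn(sb$positions, sb$positions, 2)$distance[, 2]
  expect_gte(mean(nn >= 2.7 & nn <= 3 * 2.7), 0.99)
  expect_gte(min(nn), 2 * 2.7 - 1e-9)      # hard Poisson-disc lower bound
  sb2 <- build_soft_body(s, radius = 2.7, seed = 3)
  expect_identical(sb$positions, sb2$positions)
  # every particle belongs to at least one cluster
  covered <- rep(FALSE, nrow(sb$positions))
  for (cl in sb$clusters) covered[cl$members] <- TRUE
  expect_true(all(covered))
})

test_that("uncoverable particles are reported as an error", {
  s <- sphere_mesh(r = 50, subdivisions = 3)
  expect_error(build_soft_body(s, radius = 2.7, cluster_spacing = 25,
                               cluster_radius = 6, coarse_radius = 0,
                               seed = 3),
               "not covered")
})

test_that("inflatable bookkeeping: particles, springs, volume target", {
  cb <- cube_mesh()
  infl <- build_inflatable(cb, pressure_factor = 8.5, spring_stiffness = 0.3)
  expect_identical(nrow(infl$positions), 8L)
  expect_identical(length(infl$distance$i), 18L)   # triangulated cube edges
  expect_equal(infl$volume$rest_volume, 1)
  expect_equal(infl$volume$pressure_factor, 8.5)
  expect_true(all(infl$distance$stiffness == 0.3))
  open_mesh <- triangle_mesh(diag(3), rbind(c(1, 2, 3)))
  expect_error(build_inflatable(open_mesh), "closed")
})

test_that("back fixation thresholds on the scaled viscera centre of mass", {
  ph <- make_phantom(reduced_phantom_spec(resolution = 2))
  for (sf in c(1, 0.5)) {
    scene <- build_scene(ph$wall, ph$viscera, ph$pneumo, radius = 2.7,
                         scale_factor = sf, seed = 1)
    com_y <- mesh_centroid(scene$skins$viscera$mesh)[2]
    threshold <- com_y - 20 * sf
    fixed <- scene$particles$inverse_mass == 0
    y <- scene$particles$positions[, 2]
    expect_true(all(y[fixed] < threshold))
    expect_true(all(y[!fixed] >= threshold))
    expect_gt(sum(fixed), 0)
  }
})

test_that("skin binding weights are normalised and dominant at coincidence", {
  s <- sphere_mesh(r = 10, subdivisions = 2)
  particles <- s$vertices          # particle exactly at each vertex
  b <- bind_skin(s, particles, k = 4)
  expect_equal(rowSums(b$weights), rep(1, nrow(s$vertices)))
  expect_true(all(b$weights[, 1] > 0.99))   # coincident particle dominates
  far <- rbind(c(100, 0, 0))
  m2 <- triangle_mesh(rbind(particles[1:3, ], far),
                      rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_warning(bind_skin(m2, particles[1:10, ], k = 4, radius = 1),
                 "nearest only")
})

test_that("skinning reproduces rest and is exact under translation", {
  s <- sphere_mesh(r = 10, subdivisions = 2)
  sb <- build_soft_body(s, radius = 1.5, seed = 4)
  b <- bind_skin(s, sb$positions, k = 4)
  rest <- update_skin(b, sb$positions)
  expect_lt(max(abs(rest$vertices - s$vertices)), 1e-9)
  t <- c(3, -7, 11)
  moved <- update_skin(b, sweep(sb$positions, 2, t, `+`))
  expect_lt(max(abs(moved$vertices - sweep(s$vertices, 2, t, `+`))), 1e-9)
  expect_identical(moved$faces, s$faces)
})

test_that("skinned spread follows uniform particle scaling on a 2-particle fixture", {
  particles <- rbind(c(-1, 0, 0), c(1, 0, 0))
  mesh <- triangle_mesh(rbind(c(-1, 0.1, 0), c(1, 0.1, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  b <- bind_skin(mesh, particles, k = 2)
  scaled <- update_skin(b, particles * 3)
  # vertex 1 is bound almost entirely to particle 1, vertex 2 to particle 2:
  # their x-spread scales with the particle spread (offsets constant)
  spread0 <- mesh$vertices[2, 1] - mesh$vertices[1, 1]
  spread1 <- scaled$vertices[2, 1] - scaled$vertices[1, 1]
  expect_gt(spread1 / spread0, 2.5)
  expect_lt(spread1 / spread0, 3.0 + 1e-9)
})

test_that("extract_result rescales about the scaling centre and round-trips", {
  ph <- make_phantom(reduced_phantom_spec(resolution = 2))
  scene <- build_scene(ph$wall, ph$viscera, ph$pneumo, radius = 2.7,
                       scale_factor = 0.5, seed = 1)
  half <- extract_result(scene, "pneumo", scale_back = FALSE)
  full <- extract_result(scene, "pneumo", scale_back = TRUE)
  expect_lt(max(abs(full$vertices - 2 * half$vertices)), 1e-9)
  expect_lt(max(abs(full$vertices - ph$pneumo$vertices)), 1e-6)
  expect_error(extract_result(scene, "nope"), "unknown structure")
})

test_that("phantom scene at unit pressure reproduces the inputs", {
  ph <- make_phantom(reduced_phantom_spec(resolution = 2))
  scene <- build_scene(ph$wall, ph$viscera, ph$pneumo, radius = 2.7,
                       scale_factor = 1, seed = 1)
  cfg <- experiment_config(max_steps = 100)
  sim <- simulate_scene(scene, 1, cfg)
  expect_true(sim$simulation$converged)
  for (nm in c("wall", "viscera", "pneumo")) {
    m <- extract_result(sim, nm, scale_back = TRUE)
    expect_lt(max(abs(m$vertices - ph[[nm]]$vertices)),
              2 * cfg$equilibrium_tolerance + 1e-6)
  }
})

test_that("scene serialisation round-trips and simulates identically", {
  ph <- make_phantom(mini_phantom_spec())
  scene <- build_scene(ph$wall, ph$viscera, ph$pneumo, radius = 2.7,
                       scale_factor = 1, seed = 1)
  path <- tempfile(fileext = ".json")
  save_scene(scene, path)
  scene2 <- load_scene(path)
  expect_equal(scene2$particles$positions, scene$particles$positions)
  expect_equal(scene2$constraints$distance$rest_length,
               scene$constraints$distance$rest_length)
  cfg <- experiment_config(max_steps = 30)
  s1 <- suppressWarnings(simulate_scene(scene, 2, cfg))
  s2 <- suppressWarnings(simulate_scene(scene2, 2, cfg))
  expect_equal(s1$particles$positions, s2$particles$positions,
               tolerance = 1e-12)
})
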