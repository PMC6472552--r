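test_that("distance projection matches closed-form cases", {
  st <- particle_system(rbind(c(0, 0, 0), c(2, 0, 0)), radius = 1)
  corr <- project_distance_constraint(st, 1, 2, rest_length = 1, k = 1)
  expect_equal(corr[1, ], c(0.5, 0, 0), ignore_attr = TRUE)
  expect_equal(corr[2, ], c(-0.5, 0, 0), ignore_attr = TRUE)

  st_fixed <- particle_system(rbind(c(0, 0, 0), c(2, 0, 0)),
                              inverse_mass = c(0, 1), radius = 1)
  corr <- project_distance_constraint(st_fixed, 1, 2, 1, 1)
  expect_equal(corr[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(corr[2, ], c(-1, 0, 0), ignore_attr = TRUE)

  corr <- project_distance_constraint(st, 1, 2, rest_length = 2, k = 1)
  expect_equal(max(abs(corr)), 0)

  st_co <- particle_system(rbind(c(0, 0, 0), c(0, 0, 0)), radius = 1)
  expect_warning(corr <- project_distance_constraint(st_co, 1, 2, 1, 1),
                 "coincident")
  expect_equal(max(abs(corr)), 0)
})

test_that("two-particle distance projection conserves the centroid", {
  set.seed(5)
  for (i in 1:10) {
    x <- matrix(rnorm(6), 2, 3)
    st <- particle_system(x, radius = 1)
    corr <- project_distance_constraint(st, 1, 2, rest_length = runif(1, 0.5, 2),
                                        k = runif(1))
    expect_lt(max(abs(colSums(corr))), 1e-12)
  }
})

test_that("volume projection is zero when satisfied and drives volume to target", {
  cb <- cube_mesh()
  infl <- build_inflatable(cb, pressure_factor = 1, spring_stiffness = 0)
  st <- particle_system(infl$positions, radius = 0.2)
  corr <- project_volume_constraint(st, infl$volume, k = 1)
  expect_lt(max(abs(corr)), 1e-12)

  vc2 <- infl$volume
  vc2$pressure_factor <- 2
  for (i in 1:200) {
    corr <- project_volume_constraint(st, vc2, k = 1)
    st$positions <- st$positions + corr
  }
  vol <- enclosed_volume(triangle_mesh(st$positions, cb$faces))
  expect_lt(abs(vol - 2) / 2, 0.001)

  st_all_fixed <- particle_system(infl$positions,
                                  inverse_mass = rep(0, 8), radius = 0.2)
  expect_warning(corr <- project_volume_constraint(st_all_fixed, vc2),
                 "unsatisfiable")
  expect_equal(max(abs(corr)), 0)
})

test_that("shape matching is exact for rigid motions and restores stretch", {
  set.seed(7)
  pts <- matrix(rnorm(30), 10, 3)
  cl <- shape_cluster(1:10, pts, stiffness = 1)
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st <- particle_system(pts %*% t(R) + 5, radius = 1)
  corr <- apply_shape_matching(st, cl, k = 1)
  expect_lt(max(abs(corr)), 1e-9)          # rigid motion is a fixed point

  st2 <- particle_system(pts * 1.5, radius = 1)
  corr <- apply_shape_matching(st2, cl, k = 1)
  restored <- st2$positions + corr
  cen <- colMeans(pts * 1.5)
  goal <- sweep(sweep(pts, 2, colMeans(pts)), 2, cen, `+`)
  expect_lt(max(abs(restored - goal)), 1e-6)

  corr0 <- apply_shape_matching(st2, cl, k = 0)
  expect_equal(max(abs(corr0)), 0)
})

test_that("collision projection follows inverse-mass sharing and body filters", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  st <- particle_system(pos, radius = 1, body = c(1L, 2L))
  st$rest_positions <- rbind(c(0, 0, 0), c(10, 0, 0))  # rest-far pair
  corr <- resolve_particle_collisions(st)
  expect_equal(corr[1, 1], -0.5)
  expect_equal(corr[2, 1], 0.5)

  st_same <- particle_system(pos, radius = 1, body = c(1L, 1L))
  st_same$rest_positions <- st$rest_positions
  expect_equal(max(abs(resolve_particle_collisions(st_same))), 0)

  st_fix <- particle_system(pos, inverse_mass = c(0, 1), radius = 1,
                            body = c(1L, 2L))
  st_fix$rest_positions <- st$rest_positions
  corr <- resolve_particle_collisions(st_fix)
  expect_equal(corr[1, 1], 0)
  expect_equal(corr[2, 1], 1)

  # rest-adjacent pairs may not approach beyond their rest separation
  st_adj <- particle_system(rbind(c(0, 0, 0), c(0.6, 0, 0)), radius = 1,
                            body = c(1L, 2L))
  st_adj$rest_positions <- rbind(c(0, 0, 0), c(1, 0, 0))
  corr <- resolve_particle_collisions(st_adj)
  expect_equal(corr[2, 1] - corr[1, 1], 0.4, tolerance = 1e-12)
})

test_that("a free particle under gravity falls by g dt^2 in one step", {
  st <- particle_system(matrix(0, 1, 3), radius = 1)
  cfg <- solver_config(gravity = c(0, -9810, 0), damping = 0)
  st2 <- pbd_step(st, list(), cfg)
  expect_equal(st2$positions[1, 2], -9810 * (1 / 60)^2, tolerance = 1e-12)
})

test_that("equilibrium scenes stay put and fixed particles never move", {
  cb <- cube_mesh(10)
  infl <- build_inflatable(cb, pressure_factor = 1, spring_stiffness = 0.8)
  w <- rep(1, 8)
  w[c(1, 2)] <- 0
  st <- particle_system(infl$positions, inverse_mass = w, radius = 1)
  cons <- list(distance = infl$distance, volume = infl$volume)
  st2 <- pbd_step(st, cons, solver_config())
  expect_lt(max(abs(st2$positions - st$positions)), 1e-9)

  res <- simulate_to_equilibrium(st, cons, solver_config())
  expect_true(res$converged)
  expect_identical(res$steps, 1L)

  # under load, fixed particles are bit-identical across many steps
  infl5 <- build_inflatable(cb, pressure_factor = 5, spring_stiffness = 0.5)
  st5 <- particle_system(infl5$positions, inverse_mass = w, radius = 1)
  cfg <- solver_config(max_steps = 50, equilibrium_tolerance = 1e-9)
  res5 <- suppressWarnings(simulate_to_equilibrium(
    st5, list(distance = infl5$distance, volume = infl5$volume), cfg))
  expect_identical(unname(res5$state$positions[c(1, 2), ]),
                   unname(st5$positions[c(1, 2), ]))
})

test_that("unresisted inflatables reach the target volume multiple", {
  for (fixture in list(cube_mesh(10), sphere_mesh(r = 8, subdivisions = 2))) {
    infl <- build_inflatable(fixture, spring_stiffness = 0)
    v0 <- infl$volume$rest_volume
    for (kp in c(1, 2, 5)) {
      vc <- infl$volume
      vc$pressure_factor <- kp
      st <- particle_system(infl$positions, radius = 1)
      res <- suppressWarnings(simulate_to_equilibrium(
        st, list(volume = vc),
        solver_config(max_steps = 300, equilibrium_tolerance = 1e-4)))
      vol <- enclosed_volume(triangle_mesh(res$state$positions,
                                           fixture$faces))
      expect_lt(abs(vol - kp * v0) / (kp * v0), 0.005)
    }
  }
})

test_that("equilibrium volume is monotone in the pressure parameter", {
  s <- sphere_mesh(r = 10, subdivisions = 2)
  shell <- sphere_mesh(r = 14, subdivisions = 2)
  sb <- build_soft_body(shell, radius = 1.2, cluster_stiffness = 0.6,
                        seed = 2)
  infl <- build_inflatable(s, spring_stiffness = 0.5)
  n_i <- nrow(infl$positions)
  n_s <- nrow(sb$positions)
  pos <- rbind(infl$positions, sb$positions)
  st <- particle_system(pos, radius = 1.2,
                        body = c(rep(3L, n_i), rep(1L, n_s)))
  dist <- infl$distance
  vols <- vapply(1:10, function(kp) {
    vc <- infl$volume
    vc$pressure_factor <- kp
    clusters <- lapply(sb$clusters, function(cl) {
      cl$members <- cl$members + n_i
      cl
    })
    res <- suppressWarnings(simulate_to_equilibrium(
      st, list(distance = dist, volume = vc, clusters = clusters,
               collide = TRUE),
      solver_config(max_steps = 200, equilibrium_tolerance = 5e-3,
                    damping = 0.8)))
    enclosed_volume(triangle_mesh(res$state$positions[1:n_i, ], s$faces))
  }, numeric(1))
  expect_true(all(diff(vols) > -1e-6))
})

test_that("the solver is deterministic and equivariant under rotation", {
  s <- sphere_mesh(r = 10, subdivisions = 1)
  infl <- build_inflatable(s, pressure_factor = 3, spring_stiffness = 0.5)
  st <- particle_system(infl$positions, radius = 1)
  cfg <- solver_config(max_steps = 60, equilibrium_tolerance = 1e-9)
  run <- function(state, constraints)
    suppressWarnings(simulate_to_equilibrium(state, constraints, cfg))
  r1 <- run(st, list(distance = infl$distance, volume = infl$volume))
  r2 <- run(st, list(distance = infl$distance, volume = infl$volume))
  expect_identical(r1$state$positions, r2$state$positions)  # bit-identical

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s_rot <- s
  s_rot$vertices <- s$vertices %*% t(R)
  infl_rot <- build_inflatable(s_rot, pressure_factor = 3,
                               spring_stiffness = 0.5)
  st_rot <- particle_system(infl_rot$positions, radius = 1)
  r3 <- run(st_rot, list(distance = infl_rot$distance,
                         volume = infl_rot$volume))
  expect_lt(max(abs(r3$state$positions - r1$state$positions %*% t(R))), 1e-5)
})

test_that("R reference projections agree with the compiled step", {
  # one solver iteration, distance constraints only, no damping/gravity
  set.seed(9)
  x <- matrix(rnorm(12), 4, 3)
  st <- particle_system(x, radius = 0.1)
  dc <- distance_constraints(c(1, 2), c(3, 4), c(1, 1.5), c(1, 1))
  cfg <- solver_config(solver_iterations = 1, damping = 1)
  stepped <- pbd_step(st, list(distance = dc), cfg)
  manual <- st
  for (ci in 1:2) {
    corr <- project_distance_constraint(manual, dc$i[ci], dc$j[ci],
                                        dc$rest_length[ci], 1)
    manual$positions <- manual$positions + corr
  }
  expect_lt(max(abs(stepped$positions - manual$positions)), 1e-12)
})

test_that("unreachable tolerance hits the step budget and is flagged", {
  s <- sphere_mesh(r = 5, subdivisions = 1)
  infl <- build_inflatable(s, pressure_factor = 2, spring_stiffness = 0.5)
  st <- particle_system(infl$positions, radius = 1)
  cfg <- solver_config(max_steps = 10, equilibrium_tolerance = 1e-15)
  expect_warning(res <- simulate_to_equilibrium(
    st, list(distance = infl$distance, volume = infl$volume), cfg),
    "not converged")
  expect_false(res$converged)
  expect_identical(res$steps, 10L)
})
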