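# shared fixtures: canonical meshes and the reduced phantom used by the
# simulation tests (small enough for test-time budgets, large enough for
# the particle radius grid)

cube_mesh <- function(size = 1, origin = c(0, 0, 0), name = "cube") {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * size
  v <- sweep(v, 2, origin, `+`)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0 (outward -z)
             c(5, 6, 8), c(5, 8, 7),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = 1
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = 1
  triangle_mesh(v, f, name)
}

tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  triangle_mesh(v, f, "tet")
}

sphere_mesh <- function(r = 10, subdivisions = 3, center = c(0, 0, 0)) {
  ellipsoid_mesh(c(r, r, r), center, subdivisions, name = "sphere")
}

# flat triangulated grid in the z = 0 plane, n x n vertices
grid_mesh <- function(n = 11) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  faces <- list()
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    a <- (j - 1) * n + i
    faces[[length(faces) + 1]] <- c(a, a + 1, a + n + 1)
    faces[[length(faces) + 1]] <- c(a, a + n + 1, a + n)
  }
  triangle_mesh(cbind(g$x, g$y, 0), do.call(rbind, faces), "grid")
}

# reduced phantom for simulation tests: same shape family as the default
# spec, scaled to keep particle counts tractable at radius 2.7 mm
reduced_phantom_spec <- function(resolution = 3) {
  phantom_spec(wall_outer = c(80, 60, 130), wall_thickness = 8,
               viscera = c(58, 40, 100), gap = 3, resolution = resolution)
}

# even smaller phantom for the grid-search test
mini_phantom_spec <- function() {
  phantom_spec(wall_outer = c(56, 42, 91), wall_thickness = 5.6,
               viscera = c(40.6, 28, 70), gap = 2.5, resolution = 2)
}

# quasi-static relaxation settings used by the phantom experiments
experiment_config <- function(max_steps = 600) {
  solver_config(solver_iterations = 20, damping = 1, max_steps = max_steps,
                equilibrium_tolerance = 5e-2)
}
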