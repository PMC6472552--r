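#' Sample a surface into a shape-matched soft body
#'
#' Particles are Poisson-disc sampled on the mesh surface with minimum
#' spacing `2 * radius` (deterministic for a given seed); cluster centres
#' are a Poisson-disc subset of the particles at `cluster_spacing`, and each
#' cluster contains the particles within `cluster_radius` of its centre.
#' Clusters overlap, so neighbouring clusters share particles and the body
#' deforms smoothly. A second, coarse cluster level (3x spacing and radius
#' by default) gives the surface-sampled body the long-wavelength stiffness
#' that small clusters alone cannot provide: without it a thin particle
#' shell offers almost no resistance to large smooth indentations.
#' Particles not covered by any fine cluster are attached to their nearest
#' centre when within `2 * cluster_radius`; otherwise an error lists them.
#'
#' @param mesh Surface [triangle_mesh()] (wall or viscera).
#' @param radius Particle radius in mm.
#' @param cluster_spacing Spacing of cluster centres (default `3 * radius`).
#' @param cluster_radius Cluster membership radius (default `4.5 * radius`).
#' @param cluster_stiffness Shape-matching stiffness in \[0, 1\] (shared by
#'   both levels).
#' @param coarse_spacing,coarse_radius The coarse cluster level (defaults
#'   `3 * cluster_spacing`, `3 * cluster_radius`); set `coarse_radius = 0`
#'   to disable.
#' @param seed RNG seed for the surface sampling.
#' @return A list with `positions` (P x 3) and `clusters` (list of
#'   [shape_cluster()] with indices local to `positions`).
#' @export
build_soft_body <- function(mesh, radius, cluster_spacing = 3 * radius,
                            cluster_radius = 4.5 * radius,
                            cluster_stiffness = 0.6,
                            coarse_spacing = 3 * cluster_spacing,
                            coarse_radius = 3 * cluster_radius, seed = 0) {
  stopifnot(radius > 0)
  pts <- sample_surface_points(mesh, spacing = 2 * radius, seed = seed)
  if (nrow(pts) < 3)
    stop("mesh too small to host a shape-matching cluster")
  members <- cluster_members(pts, cluster_spacing, cluster_radius)
  if (length(members) == 0)
    stop("mesh too small to host a shape-matching cluster")
  covered <- rep(FALSE, nrow(pts))
  for (m in members) covered[m] <- TRUE
  if (any(!covered)) {
    orphans <- which(!covered)
    cen_mat <- do.call(rbind, lapply(members, function(m)
      colMeans(pts[m, , drop = FALSE])))
    nn <- cpp_knn(pts[orphans, , drop = FALSE], cen_mat, 1L)
    too_far <- nn$distance[, 1] > 2 * cluster_radius
    if (any(too_far))
      stop("particles not covered by any cluster: ",
           paste(orphans[too_far], collapse = ", "),
           " (increase cluster_radius)")
    for (k in seq_along(orphans))
      members[[nn$index[k, 1]]] <- c(members[[nn$index[k, 1]]], orphans[k])
  }
  if (coarse_radius > 0)
    members <- c(members, cluster_members(pts, coarse_spacing, coarse_radius))
  clusters <- lapply(members, function(m)
    shape_cluster(m, pts[m, , drop = FALSE], stiffness = cluster_stiffness))
  list(positions = pts, clusters = clusters)
}

# Poisson-disc cluster centres over the particles + radius membership
cluster_members <- function(pts, spacing, radius) {
  keep <- cpp_poisson_filter(pts, spacing)
  centres <- pts[keep, , drop = FALSE]
  members <- lapply(seq_len(nrow(centres)), function(ci) {
    d2 <- rowSums(sweep(pts, 2, centres[ci, ])^2)
    which(d2 <= radius^2)
  })
  members[vapply(members, length, 1L) >= 3]
}

# Area-weighted candidate generation + greedy Poisson-disc thinning.
# Deterministic for a given seed; candidate density ~6 per disc ensures
# near-maximal packing.
sample_surface_points <- function(mesh, spacing, seed = 0) {
  areas <- mesh_face_areas(mesh)
  total <- sum(areas)
  n_cand <- max(100L, ceiling(6 * total / (pi * (spacing / 2)^2)))
  with_local_seed(seed, {
    fi <- sample.int(nrow(mesh$faces), n_cand, replace = TRUE,
                     prob = areas / total)
    u <- runif(n_cand)
    v <- runif(n_cand)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    cand <- a + u * (b - a) + v * (cc - a)
    keep <- cpp_poisson_filter(cand, spacing)
    cand[keep, , drop = FALSE]
  })
}

#' Build the inflatable from the deflated cavity mesh
#'
#' One particle per mesh vertex; one distance (cloth spring) constraint per
#' unique edge at its rest length plus one bending link per interior edge
#' (between the two vertices opposite the shared edge of adjacent
#' triangles, the standard particle-cloth bending model); and one global
#' volume constraint over all faces with rest volume V0 equal to the
#' enclosed volume of the deflated mesh and target `pressure_factor * V0`.
#'
#' @param mesh Closed deflated pneumoperitoneum [triangle_mesh()].
#' @param pressure_factor The simulation pressure parameter k_p.
#' @param spring_stiffness Cloth spring stiffness in \[0, 1\].
#' @param bend_stiffness Stiffness of the bending links (default 0: pure
#'   stretch cloth).
#' @param volume_stiffness Stiffness of the volume projection (default 1).
#' @return A list with `positions`, `distance` ([distance_constraints()])
#'   and `volume` ([volume_constraint()]).
#' @export
build_inflatable <- function(mesh, pressure_factor = 1,
                             spring_stiffness = 0.5,
                             bend_stiffness = 0,
                             volume_stiffness = 1) {
  nb <- mesh_boundary_edge_count(mesh)
  if (nb > 0)
    stop("inflatable mesh must be closed (", nb, " boundary edges)")
  v0 <- enclosed_volume(mesh)
  e <- mesh_edges(mesh)
  dist_i <- e[, 1]
  dist_j <- e[, 2]
  stiff <- rep(spring_stiffness, nrow(e))
  if (bend_stiffness > 0) {
    bend <- bending_pairs(mesh$faces)
    dist_i <- c(dist_i, bend[, 1])
    dist_j <- c(dist_j, bend[, 2])
    stiff <- c(stiff, rep(bend_stiffness, nrow(bend)))
  }
  rest <- sqrt(rowSums((mesh$vertices[dist_i, , drop = FALSE] -
                          mesh$vertices[dist_j, , drop = FALSE])^2))
  list(positions = mesh$vertices,
       distance = distance_constraints(dist_i, dist_j, rest, stiff),
       volume = volume_constraint(mesh$faces, v0, pressure_factor,
                                  volume_stiffness))
}

# opposite-vertex pairs across each interior edge (bending links)
bending_pairs <- function(faces) {
  f <- faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  opp <- c(f[, 3], f[, 1], f[, 2])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ord <- order(key)
  key <- key[ord]
  opp <- opp[ord]
  same <- key[-1] == key[-length(key)]
  cbind(opp[c(same, FALSE)], opp[c(FALSE, same)])
}

#' Bind a surface mesh to particles (skinning)
#'
#' Each mesh vertex is bound to its `k` nearest particles at rest with
#' inverse-distance weights `w_i ~ 1 / (d_i + 1e-6)` (normalised to sum to
#' 1) and per-particle rest offsets, so the skinned surface follows the
#' deformed particle set by translation-blend linear skinning. A vertex
#' farther than `10 * radius` from every particle is bound to its nearest
#' particle only, with a warning.
#'
#' @param mesh Surface [triangle_mesh()].
#' @param positions Particle rest positions (P x 3).
#' @param k Number of particles bound per vertex (default 4).
#' @param radius Particle radius used for the distance sanity check.
#' @return A `skin_binding` object.
#' @export
bind_skin <- function(mesh, positions, k = 4, radius = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("no particles to bind to")
  k <- min(k, nrow(positions))
  nn <- cpp_knn(mesh$vertices, positions, k)
  eps <- 1e-6
  w <- 1 / (nn$distance + eps)
  if (!is.null(radius)) {
    far <- nn$distance[, 1] > 10 * radius
    if (any(far)) {
      warning(sum(far), " vertex/vertices farther than 10*radius from all ",
              "particles: bound to nearest only")
      w[far, -1] <- 0
    }
  }
  w <- w / rowSums(w)
  n <- nrow(mesh$vertices)
  offsets <- array(0, dim = c(n, k, 3))
  for (kk in seq_len(k))
    offsets[, kk, ] <- mesh$vertices - positions[nn$index[, kk], , drop = FALSE]
  structure(list(index = nn$index, weights = w, offsets = offsets,
                 faces = mesh$faces, name = mesh$name),
            class = "skin_binding")
}

#' Evaluate a skin binding against current particle positions
#'
#' Vertex positions are the weight-blended sum of bound particle positions
#' plus stored rest offsets; topology is unchanged. With particles at rest
#' this reproduces the rest mesh exactly.
#'
#' @param binding A [bind_skin()] result.
#' @param positions Current particle positions (same indexing as at bind
#'   time).
#' @return A [triangle_mesh()].
#' @export
update_skin <- function(binding, positions) {
  positions <- as.matrix(positions)
  n <- nrow(binding$index)
  k <- ncol(binding$index)
  v <- matrix(0, n, 3)
  for (kk in seq_len(k)) {
    p <- positions[binding$index[, kk], , drop = FALSE]
    v <- v + binding$weights[, kk] * (p + binding$offsets[, kk, ])
  }
  triangle_mesh(v, binding$faces, name = binding$name)
}

#' Build a complete simulation scene from the three structure meshes
#'
#' Scales all meshes by `scale_factor` about `scale_center` (the half-scale
#' workflow), samples the wall and viscera into shape-matched soft bodies,
#' builds the inflatable from the deflated cavity mesh, fixes the back
#' particles (below the viscera centre of mass minus `fixed_offset`, on the
#' anterior/posterior y-axis; the supine convention with +y anterior must
#' hold for the inputs), and binds each input mesh to its body's particles
#' for result extraction.
#'
#' @param wall,viscera,pneumo The three segmented [triangle_mesh()]es, in
#'   mm, supine +y-anterior orientation.
#' @param radius Particle radius in mm.
#' @param cluster_stiffness Soft-body shape-matching stiffness (one value
#'   shared by wall and viscera, as in the calibration).
#' @param spring_stiffness Inflatable cloth stiffness.
#' @param pressure_factor Initial simulation pressure parameter.
#' @param scale_factor Uniform pre-simulation scale (default 0.5).
#' @param scale_center Centre of scaling (default origin).
#' @param fixed_offset Fixation plane offset below the viscera centre of
#'   mass, in original-scale mm (default 20).
#' @param seed Sampling seed.
#' @param cluster_spacing,cluster_radius Soft-body clustering parameters
#'   (defaults `3 * radius`, `4.5 * radius`).
#' @return A `pneumo_scene` object.
#' @export
build_scene <- function(wall, viscera, pneumo, radius = 2.7,
                        cluster_stiffness = 0.6, spring_stiffness = 0.5,
                        pressure_factor = 1, scale_factor = 0.5,
                        scale_center = c(0, 0, 0), fixed_offset = 20,
                        seed = 0, cluster_spacing = 3 * radius,
                        cluster_radius = 4.5 * radius) {
  wall_s <- scale_mesh(wall, scale_factor, scale_center)
  visc_s <- scale_mesh(viscera, scale_factor, scale_center)
  pneu_s <- scale_mesh(pneumo, scale_factor, scale_center)

  sb_wall <- build_soft_body(wall_s, radius, cluster_spacing, cluster_radius,
                             cluster_stiffness, seed = seed + 1L)
  sb_visc <- build_soft_body(visc_s, radius, cluster_spacing, cluster_radius,
                             cluster_stiffness, seed = seed + 2L)
  infl <- build_inflatable(pneu_s, pressure_factor, spring_stiffness)

  n_w <- nrow(sb_wall$positions)
  n_v <- nrow(sb_visc$positions)
  n_i <- nrow(infl$positions)
  positions <- rbind(sb_wall$positions, sb_visc$positions, infl$positions)
  body <- c(rep(BODY_WALL, n_w), rep(BODY_VISCERA, n_v),
            rep(BODY_INFLATABLE, n_i))
  state <- particle_system(positions, radius = radius, body = body)

  shift_cluster <- function(cl, off) {
    cl$members <- cl$members + off
    cl
  }
  clusters <- c(lapply(sb_wall$clusters, shift_cluster, off = 0L),
                lapply(sb_visc$clusters, shift_cluster, off = n_w))
  dist <- infl$distance
  dist$i <- dist$i + n_w + n_v
  dist$j <- dist$j + n_w + n_v
  vol <- infl$volume
  vol$faces <- vol$faces + n_w + n_v

  idx_of <- function(first, n) seq.int(first, length.out = n)
  skins <- list(
    wall = list(binding = bind_skin(wall_s, sb_wall$positions,
                                    radius = radius),
                particle_index = idx_of(1L, n_w), mesh = wall_s),
    viscera = list(binding = bind_skin(visc_s, sb_visc$positions,
                                       radius = radius),
                   particle_index = idx_of(n_w + 1L, n_v), mesh = visc_s),
    pneumo = list(binding = bind_skin(pneu_s, infl$positions,
                                      radius = radius),
                  particle_index = idx_of(n_w + n_v + 1L, n_i),
                  mesh = pneu_s))

  scene <- structure(list(
    particles = state,
    constraints = list(distance = dist, volume = vol, clusters = clusters,
                       collide = TRUE),
    skins = skins,
    provenance = list(meshes = c(wall = wall$name, viscera = viscera$name,
                                 pneumo = pneumo$name),
                      scale_factor = scale_factor,
                      scale_center = as.numeric(scale_center),
                      seed = seed, radius = radius,
                      cluster_stiffness = cluster_stiffness,
                      spring_stiffness = spring_stiffness,
                      fixed_offset = fixed_offset)),
    class = "pneumo_scene")
  select_fixed_particles(scene, offset = fixed_offset)
}

#' @export
print.pneumo_scene <- function(x, ...) {
  cat(sprintf(paste0("pneumo_scene: %d particles (%d fixed), %d springs, ",
                     "%d clusters, scale %g\n"),
              nrow(x$particles$positions), sum(x$particles$inverse_mass == 0),
              length(x$constraints$distance$i),
              length(x$constraints$clusters),
              x$provenance$scale_factor))
  invisible(x)
}

#' Fix the back particles of a scene
#'
#' Every particle (of any body) whose y-coordinate lies below the viscera
#' centre of mass minus `offset` (given in original-scale mm and multiplied
#' by the scene's scale factor) gets inverse mass 0 and never moves. This
#' anchors the posterior region, emulating the supine subject resting on
#' the table.
#'
#' @param scene A [build_scene()] result.
#' @param offset Plane offset in original-scale mm (default 20).
#' @return The scene with updated inverse masses.
#' @export
select_fixed_particles <- function(scene, offset = 20) {
  com <- mesh_centroid(scene$skins$viscera$mesh)
  threshold <- com[2] - offset * scene$provenance$scale_factor
  fixed <- scene$particles$positions[, 2] < threshold
  scene$particles$inverse_mass[fixed] <- 0
  scene$particles$inverse_mass[!fixed] <- 1
  if (!any(fixed))
    warning("no particles fixed: scene is free floating")
  scene$provenance$n_fixed <- sum(fixed)
  scene
}

#' Simulate a scene to equilibrium at a given pressure parameter
#'
#' @param scene A [build_scene()] result.
#' @param pressure_factor Simulation pressure parameter k_p (volume
#'   multiple of the deflated cavity).
#' @param config A [solver_config()].
#' @return The scene, with updated particle state and a `simulation` field
#'   (`steps`, `residual`, `converged`, `pressure_factor`).
#' @export
simulate_scene <- function(scene, pressure_factor,
                           config = solver_config()) {
  scene$constraints$volume$pressure_factor <- pressure_factor
  res <- simulate_to_equilibrium(scene$particles, scene$constraints, config)
  scene$particles <- res$state
  scene$simulation <- list(steps = res$steps, residual = res$residual,
                           converged = res$converged,
                           pressure_factor = pressure_factor)
  scene
}

#' Extract a deformed surface mesh from a scene
#'
#' Evaluates the skin binding of the named structure against the current
#' particle positions and, when `scale_back` is true, rescales the result
#' by `1 / scale_factor` about the scene's scaling centre so it compares
#' directly with original-size reference meshes.
#'
#' @param scene A simulated scene.
#' @param name One of `"wall"`, `"viscera"`, `"pneumo"`.
#' @param scale_back Undo the build-time scaling (default TRUE).
#' @return A [triangle_mesh()].
#' @export
extract_result <- function(scene, name, scale_back = TRUE) {
  skin <- scene$skins[[name]]
  if (is.null(skin))
    stop("unknown structure '", name, "'; available: ",
         paste(names(scene$skins), collapse = ", "))
  pos <- scene$particles$positions[skin$particle_index, , drop = FALSE]
  mesh <- update_skin(skin$binding, pos)
  if (scale_back)
    mesh <- scale_mesh(mesh, 1 / scene$provenance$scale_factor,
                       scene$provenance$scale_center)
  mesh
}
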