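#' Particle system state
#'
#' The position-based-dynamics state: particle positions, previous
#' positions (implicit velocities), inverse masses (0 marks a fixed
#' particle), one global particle radius, and a body label per particle.
#'
#' @param positions N x 3 numeric matrix (mm).
#' @param inverse_mass Numeric vector of length N, >= 0; 0 fixes a particle.
#' @param radius Particle radius in mm (single value for the whole scene,
#'   the calibration grid uses 2.2, 2.7 or 3.3 mm).
#' @param body Integer body labels, see [body_labels()].
#' @param previous_positions N x 3 matrix; defaults to `positions` (zero
#'   initial velocity).
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, inverse_mass = NULL, radius = 2.7,
                            body = NULL, previous_positions = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (is.null(inverse_mass)) inverse_mass <- rep(1, n)
  if (is.null(body)) body <- rep(BODY_INFLATABLE, n)
  if (is.null(previous_positions)) previous_positions <- positions
  stopifnot(ncol(positions) == 3, length(inverse_mass) == n,
            all(inverse_mass >= 0), radius > 0, length(body) == n)
  structure(list(positions = positions,
                 previous_positions = as.matrix(previous_positions),
                 inverse_mass = as.numeric(inverse_mass),
                 radius = as.numeric(radius),
                 body = as.integer(body),
                 rest_positions = positions),
            class = "particle_system")
}

#' Constraint constructors
#'
#' `distance_constraints()` builds the cloth-spring constraints of the
#' inflatable: one per unique mesh edge, with a rest length and a stiffness
#' in \[0, 1\] (the "spring stiffness" calibration parameter).
#' `volume_constraint()` is the global inflatable constraint: the enclosed
#' volume of `faces` over the particle positions is driven to
#' `pressure_factor * rest_volume`; `pressure_factor` is the dimensionless
#' "simulation pressure parameter" (an overpressure volume multiplier, not a
#' physical pressure). `shape_cluster()` groups particles into an elastic
#' shape-matching cluster with a stiffness in \[0, 1\] (the "cluster
#' stiffness" parameter).
#'
#' @param i,j Particle index vectors (1-based), `i != j` elementwise.
#' @param rest_length Rest lengths in mm, > 0.
#' @param stiffness Stiffness in \[0, 1\]. The solver applies the
#'   iteration-corrected value `1 - (1 - k)^(1/n_iter)` so results are
#'   insensitive to the solver iteration count.
#' @return A list-based constraint object.
#' @export
distance_constraints <- function(i, j, rest_length, stiffness) {
  stopifnot(length(i) == length(j), all(i != j), all(rest_length > 0),
            all(stiffness >= 0), all(stiffness <= 1))
  structure(list(i = as.integer(i), j = as.integer(j),
                 rest_length = as.numeric(rest_length),
                 stiffness = rep_len(as.numeric(stiffness), length(i))),
            class = "distance_constraints")
}

#' @rdname distance_constraints
#' @param faces Triangle index triples (1-based) forming a closed oriented
#'   surface over the particles.
#' @param rest_volume Rest enclosed volume V0 in mm^3, > 0.
#' @param pressure_factor Target volume multiple k_p >= 0.
#' @export
volume_constraint <- function(faces, rest_volume, pressure_factor = 1,
                              stiffness = 1) {
  stopifnot(rest_volume > 0, pressure_factor >= 0, stiffness >= 0,
            stiffness <= 1)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  structure(list(faces = faces, rest_volume = as.numeric(rest_volume),
                 pressure_factor = as.numeric(pressure_factor),
                 stiffness = as.numeric(stiffness)),
            class = "volume_constraint")
}

#' @rdname distance_constraints
#' @param members Particle indices (>= 3, non-collinear).
#' @param rest_positions Member rest positions (used to compute rest
#'   offsets about the rest centroid).
#' @export
shape_cluster <- function(members, rest_positions, stiffness) {
  members <- as.integer(members)
  stopifnot(length(members) >= 3, stiffness >= 0, stiffness <= 1)
  rest_positions <- as.matrix(rest_positions)
  stopifnot(nrow(rest_positions) == length(members))
  centroid <- colMeans(rest_positions)
  offs <- sweep(rest_positions, 2, centroid)
  if (qr(offs)$rank < 2)
    warning("collinear shape cluster: rotation is ill-defined")
  structure(list(members = members, rest_offsets = offs,
                 rest_centroid = centroid,
                 stiffness = as.numeric(stiffness)),
            class = "shape_cluster")
}

#' Solver configuration
#'
#' @param time_step Integration step in seconds (default 1/60).
#' @param solver_iterations Constraint projection rounds per step.
#' @param gravity 3-vector in mm/s^2; zero by default (the insufflation
#'   model neglects gravity).
#' @param collision_margin Extra separation added to the 2*radius contact
#'   distance (mm).
#' @param equilibrium_tolerance Maximum per-step particle displacement (mm)
#'   below which the scene counts as at rest.
#' @param max_steps Step budget for [simulate_to_equilibrium()].
#' @param damping Velocity damping per step in \[0, 1\].
#' @return A `solver_config` list.
#' @export
solver_config <- function(time_step = 1 / 60, solver_iterations = 30,
                          gravity = c(0, 0, 0), collision_margin = 0,
                          equilibrium_tolerance = 1e-3, max_steps = 1000,
                          damping = 0.05) {
  stopifnot(time_step > 0, solver_iterations >= 1,
            equilibrium_tolerance > 0 || equilibrium_tolerance == 0,
            length(gravity) == 3, damping >= 0, damping <= 1)
  structure(list(time_step = time_step,
                 solver_iterations = as.integer(solver_iterations),
                 gravity = as.numeric(gravity),
                 collision_margin = collision_margin,
                 equilibrium_tolerance = equilibrium_tolerance,
                 max_steps = as.integer(max_steps),
                 damping = damping),
            class = "solver_config")
}

# ---- single-constraint reference projections (pure R) ------------------

#' Project a single distance constraint
#'
#' Reference (pure R) implementation of the classic PBD distance
#' projection: corrections proportional to inverse masses along the
#' separation direction, scaled by the (already iteration-corrected)
#' stiffness `k`. Fixed particles receive zero correction.
#'
#' @param state A [particle_system()].
#' @param i,j Particle indices.
#' @param rest_length Rest length (mm).
#' @param k Effective stiffness in \[0, 1\].
#' @return N x 3 matrix of position corrections.
#' @export
project_distance_constraint <- function(state, i, j, rest_length, k = 1) {
  x <- state$positions
  w <- state$inverse_mass
  corr <- matrix(0, nrow(x), 3)
  d <- x[i, ] - x[j, ]
  len <- sqrt(sum(d^2))
  if (len < 1e-9) {
    warning("coincident particles in distance constraint: skipped")
    return(corr)
  }
  wsum <- w[i] + w[j]
  if (wsum <= 0) return(corr)
  s <- k * (len - rest_length) / (len * wsum)
  corr[i, ] <- -w[i] * s * d
  corr[j, ] <- +w[j] * s * d
  corr
}

#' Project the global volume constraint
#'
#' Reference (pure R) implementation: the constraint function is
#' `C = V(x) - k_p * V0`; corrections follow the scaled negative gradient,
#' `dx_i = -s * w_i * grad_i C` with `s = C / sum_j w_j |grad_j C|^2`.
#'
#' @param state A [particle_system()].
#' @param vc A [volume_constraint()].
#' @param k Effective stiffness in \[0, 1\].
#' @return N x 3 matrix of position corrections.
#' @export
project_volume_constraint <- function(state, vc, k = 1) {
  x <- state$positions
  w <- state$inverse_mass
  f <- vc$faces
  corr <- matrix(0, nrow(x), 3)
  a <- x[f[, 1], , drop = FALSE]
  b <- x[f[, 2], , drop = FALSE]
  cc <- x[f[, 3], , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  vol <- sum(rowSums(cross(a, b) * cc)) / 6
  C <- vol - vc$pressure_factor * vc$rest_volume
  grad <- matrix(0, nrow(x), 3)
  gb <- cross(b, cc) / 6
  gc <- cross(cc, a) / 6
  ga <- cross(a, b) / 6
  for (col in 1:3) {
    grad[, col] <- grad[, col] +
      tabulate_sum(f[, 1], gb[, col], nrow(x)) +
      tabulate_sum(f[, 2], gc[, col], nrow(x)) +
      tabulate_sum(f[, 3], ga[, col], nrow(x))
  }
  denom <- sum(w * rowSums(grad^2))
  if (denom < 1e-12) {
    warning("volume constraint unsatisfiable: all particles fixed")
    return(corr)
  }
  s <- C / denom
  -k * s * w * grad
}

tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Apply shape matching to a cluster
#'
#' Reference (pure R) implementation: fits the rotation of the rest shape
#' to the current member positions by polar decomposition of the moment
#' matrix (SVD with reflection guard) and moves members a `stiffness`
#' fraction towards their goal positions. Fixed members contribute to the
#' fit but receive no correction.
#'
#' @param state A [particle_system()].
#' @param cluster A [shape_cluster()].
#' @param k Effective stiffness in \[0, 1\].
#' @return N x 3 matrix of position corrections.
#' @export
apply_shape_matching <- function(state, cluster, k = cluster$stiffness) {
  x <- state$positions
  w <- state$inverse_mass
  corr <- matrix(0, nrow(x), 3)
  m <- cluster$members
  cur <- x[m, , drop = FALSE]
  cen <- colMeans(cur)
  A <- t(sweep(cur, 2, cen)) %*% cluster$rest_offsets
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  if (sv$d[1] < 1e-12) R <- diag(3)  # degenerate: identity fallback
  goal <- sweep(cluster$rest_offsets %*% t(R), 2, cen, `+`)
  delta <- k * (goal - cur)
  delta[w[m] <= 0, ] <- 0
  corr[m, ] <- delta
  corr
}

#' Resolve inter-body particle collisions
#'
#' Reference (pure R, O(n^2)) implementation: particle pairs from different
#' bodies closer than their contact distance are pushed apart along their
#' separation direction proportionally to inverse masses, until the
#' separation equals the contact distance. The contact distance is
#' `2 * radius + margin`, capped at the pair's rest separation: adjacent
#' structures that already overlap in the rest pose may not approach
#' beyond their rest separation but are not pushed apart. Same-body pairs
#' are ignored.
#'
#' @param state A [particle_system()].
#' @param margin Extra separation in mm.
#' @return N x 3 matrix of position corrections.
#' @export
resolve_particle_collisions <- function(state, margin = 0) {
  x <- state$positions
  w <- state$inverse_mass
  n <- nrow(x)
  dc <- 2 * state$radius + margin
  corr <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (state$body[i] == state$body[j]) next
      wsum <- w[i] + w[j]
      if (wsum <= 0) next
      d <- x[i, ] - x[j, ]
      len <- sqrt(sum(d^2))
      r <- state$rest_positions[i, ] - state$rest_positions[j, ]
      pdc <- min(dc, sqrt(sum(r^2)))
      if (len >= pdc) next
      if (len < 1e-9) {
        warning("coincident colliding particles: separating along x")
        d <- c(1, 0, 0)
        len <- 1
      }
      s <- (pdc - len) / (len * wsum)
      corr[i, ] <- corr[i, ] + w[i] * s * d
      corr[j, ] <- corr[j, ] - w[j] * s * d
    }
  }
  corr
}

# ---- stepping ----------------------------------------------------------

# pack constraints and call the C++ core
pbd_run_core <- function(state, constraints, config, max_steps, tol) {
  dc <- constraints$distance
  vc <- constraints$volume
  clusters <- constraints$clusters
  if (is.null(dc)) dc <- distance_constraints(integer(), integer(),
                                              numeric(), numeric())
  if (is.null(clusters)) clusters <- list()
  ij <- cbind(dc$i, dc$j) - 1L
  if (nrow(ij) == 0) ij <- matrix(integer(), 0, 2)
  if (is.null(vc)) {
    vfaces <- matrix(integer(), 0, 3)
    v0 <- 1; kp <- 1; vstiff <- 0
  } else {
    vfaces <- vc$faces - 1L
    v0 <- vc$rest_volume
    kp <- vc$pressure_factor
    vstiff <- vc$stiffness
  }
  nm <- vapply(clusters, function(cl) length(cl$members), 1L)
  cl_ptr <- c(0L, cumsum(nm))
  cl_members <- if (length(clusters))
    unlist(lapply(clusters, function(cl) cl$members)) - 1L else integer()
  cl_offsets <- if (length(clusters))
    do.call(rbind, lapply(clusters, function(cl) cl$rest_offsets)) else
      matrix(0, 0, 3)
  cl_stiff <- vapply(clusters, function(cl) cl$stiffness, 1.0)
  cfg <- list(time_step = config$time_step,
              solver_iterations = config$solver_iterations,
              damping = config$damping,
              gravity = config$gravity,
              collision_margin = config$collision_margin,
              equilibrium_tolerance = tol,
              max_steps = as.integer(max_steps),
              collide = isTRUE(constraints$collide))
  res <- cpp_pbd_run(state$positions, state$previous_positions,
                     state$inverse_mass, state$body, state$radius,
                     state$rest_positions, ij, dc$rest_length, dc$stiffness,
                     vfaces, v0, kp, vstiff,
                     cl_ptr, cl_members, cl_offsets, cl_stiff, cfg)
  state$positions <- res$positions
  state$previous_positions <- res$previous_positions
  list(state = state, steps = res$steps, residual = res$residual,
       converged = res$converged)
}

#' Advance the simulation by one step
#'
#' Semi-implicit prediction (damped velocity, gravity), then
#' `solver_iterations` Gauss-Seidel rounds projecting, in order: distance
#' constraints, the volume constraint, shape-matching clusters, and
#' inter-body collisions; velocities then follow from the position delta.
#' Fixed particles are bit-identical before and after.
#'
#' @param state A [particle_system()].
#' @param constraints A list with optional elements `distance`
#'   ([distance_constraints()]), `volume` ([volume_constraint()]),
#'   `clusters` (list of [shape_cluster()]), and logical `collide`.
#' @param config A [solver_config()].
#' @return The updated [particle_system()].
#' @export
pbd_step <- function(state, constraints, config = solver_config()) {
  pbd_run_core(state, constraints, config, max_steps = 1, tol = -1)$state
}

#' Run the solver until mechanical equilibrium
#'
#' Steps until the maximum per-step particle displacement falls below
#' `config$equilibrium_tolerance`, or `config$max_steps` is reached (the
#' result is then flagged as not converged). Deterministic: identical
#' inputs give bit-identical trajectories.
#'
#' @inheritParams pbd_step
#' @return A list with `state`, `steps`, `residual` (mm, last step's max
#'   displacement) and logical `converged`.
#' @export
simulate_to_equilibrium <- function(state, constraints,
                                    config = solver_config()) {
  tol <- config$equilibrium_tolerance
  res <- pbd_run_core(state, constraints, config,
                      max_steps = config$max_steps,
                      tol = if (tol > 0) tol else -1)
  if (!res$converged && tol > 0)
    warning("not converged after ", res$steps, " steps (residual ",
            signif(res$residual, 3), " mm)")
  res
}
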