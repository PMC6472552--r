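#' Calibration grid specification
#'
#' The four-dimensional exhaustive-search grid over cluster stiffness,
#' spring stiffness, particle radius and the simulation pressure parameter.
#' Defaults are the full calibration ranges; reduced grids are built by
#' passing shorter vectors.
#'
#' @param cluster_stiffness Soft-body stiffness values in \[0, 1\].
#' @param spring_stiffness Inflatable cloth stiffness values in \[0, 1\].
#' @param particle_radius Particle radii in mm.
#' @param pressure Simulation pressure parameter values.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(cluster_stiffness = c(0.4, 0.5, 0.6, 0.7, 0.8),
                      spring_stiffness = seq(0.1, 1.0, by = 0.1),
                      particle_radius = c(2.2, 2.7, 3.3),
                      pressure = seq(1.0, 15.0, by = 0.5)) {
  stopifnot(length(cluster_stiffness) > 0, length(spring_stiffness) > 0,
            length(particle_radius) > 0, length(pressure) > 0,
            all(cluster_stiffness >= 0 & cluster_stiffness <= 1),
            all(spring_stiffness >= 0 & spring_stiffness <= 1),
            all(particle_radius > 0))
  structure(list(cluster_stiffness = sort(as.numeric(cluster_stiffness)),
                 spring_stiffness = sort(as.numeric(spring_stiffness)),
                 particle_radius = sort(as.numeric(particle_radius)),
                 pressure = sort(as.numeric(pressure))),
            class = "grid_spec")
}

#' Exhaustive calibration grid search
#'
#' For every (cluster stiffness, spring stiffness, particle radius) the
#' scene of each subject is rebuilt; for every pressure value the model is
#' simulated to equilibrium, the inflatable skin extracted, rescaled to
#' original size and scored against the subject's reference
#' pneumoperitoneum with [mean_nearest_vertex_distance()]. The winning
#' parameter set minimises the subject-averaged per-subject minima (over
#' pressure); ties break towards the lexicographically smallest parameter
#' tuple. Non-converged simulations are recorded as `NA` with a warning
#' and a parameter set containing any `NA` cannot win.
#'
#' @param subjects List of subjects, each a list with `wall`, `viscera`,
#'   `pneumo` (deflated meshes) and `reference` (inflated reference
#'   pneumoperitoneum mesh, original scale).
#' @param grid A [grid_spec()].
#' @param config A [solver_config()].
#' @param scale_factor Pre-simulation scale (default 0.5).
#' @param seed Sampling seed.
#' @param fixed_offset Back-fixation offset in mm (default 20).
#' @return A `calibration_result`: list with the full error `tensor`
#'   (data frame: subject, cluster_stiffness, spring_stiffness,
#'   particle_radius, pressure, error, converged), the per-parameter-set
#'   `summary`, the winning `best` parameters and `per_subject` minima at
#'   those parameters.
#' @export
run_grid_search <- function(subjects, grid = grid_spec(),
                            config = solver_config(), scale_factor = 0.5,
                            seed = 0, fixed_offset = 20) {
  stopifnot(length(subjects) >= 1)
  rows <- list()
  for (r in grid$particle_radius) {
    for (cs in grid$cluster_stiffness) {
      for (ss in grid$spring_stiffness) {
        for (si in seq_along(subjects)) {
          sub <- subjects[[si]]
          scene <- build_scene(sub$wall, sub$viscera, sub$pneumo,
                               radius = r, cluster_stiffness = cs,
                               spring_stiffness = ss,
                               scale_factor = scale_factor, seed = seed,
                               fixed_offset = fixed_offset)
          for (kp in grid$pressure) {
            sim <- withCallingHandlers(
              simulate_scene(scene, kp, config),
              warning = function(w) invokeRestart("muffleWarning"))
            err <- NA_real_
            if (sim$simulation$converged) {
              mesh <- extract_result(sim, "pneumo", scale_back = TRUE)
              err <- mean_nearest_vertex_distance(mesh, sub$reference)
            } else {
              warning("simulation did not converge at (", cs, ", ", ss,
                      ", ", r, ", ", kp, "), subject ", si,
                      ": recorded as missing")
            }
            rows[[length(rows) + 1]] <- data.frame(
              subject = si, cluster_stiffness = cs, spring_stiffness = ss,
              particle_radius = r, pressure = kp, error = err,
              converged = sim$simulation$converged)
          }
        }
      }
    }
  }
  tensor <- do.call(rbind, rows)
  summarise_calibration(tensor)
}

# aggregate an error tensor into the calibration result
summarise_calibration <- function(tensor) {
  params <- unique(tensor[, c("cluster_stiffness", "spring_stiffness",
                              "particle_radius")])
  params <- params[order(params$cluster_stiffness, params$spring_stiffness,
                         params$particle_radius), , drop = FALSE]
  avg_min <- vapply(seq_len(nrow(params)), function(pi) {
    sel <- tensor$cluster_stiffness == params$cluster_stiffness[pi] &
      tensor$spring_stiffness == params$spring_stiffness[pi] &
      tensor$particle_radius == params$particle_radius[pi]
    sub_tensor <- tensor[sel, ]
    if (anyNA(sub_tensor$error)) return(Inf)  # NA cells disqualify the set
    mins <- tapply(sub_tensor$error, sub_tensor$subject, min)
    mean(mins)
  }, numeric(1))
  summary <- cbind(params, avg_min_error = avg_min)
  best_i <- which.min(avg_min)  # params pre-sorted: ties break lexicographic
  best <- as.list(params[best_i, ])
  sel <- tensor$cluster_stiffness == best$cluster_stiffness &
    tensor$spring_stiffness == best$spring_stiffness &
    tensor$particle_radius == best$particle_radius
  bt <- tensor[sel, ]
  per_subject <- do.call(rbind, lapply(split(bt, bt$subject), function(d) {
    d <- d[order(d$pressure), ]
    ok <- !is.na(d$error)
    i <- which(d$error == min(d$error[ok]) & ok)[1]  # ties: smaller pressure
    data.frame(subject = d$subject[1], min_error = d$error[i],
               pressure = d$pressure[i])
  }))
  rownames(per_subject) <- NULL
  structure(list(tensor = tensor, summary = summary, best = best,
                 per_subject = per_subject),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result: best parameters\n")
  cat(sprintf("  cluster stiffness %g, spring stiffness %g, radius %g mm\n",
              x$best$cluster_stiffness, x$best$spring_stiffness,
              x$best$particle_radius))
  print(x$per_subject)
  invisible(x)
}

#' Match simulation pressure parameters to experimental pressures
#'
#' Given, per experimental pressure, an error curve over the simulation
#' pressure parameter (typically the voxel non-overlap error), returns the
#' parameter at the minimum of each curve. Ties break towards the smaller
#' parameter; a flat curve or a minimum at the curve boundary is reported
#' with a warning.
#'
#' @param error_curves Named list (names: pressures in mmHg); each element
#'   a data frame with columns `pressure_parameter` and `error`.
#' @return Data frame with `mmHg`, `pressure_parameter`, `error`.
#' @export
match_pressures <- function(error_curves) {
  stopifnot(length(error_curves) > 0)
  rows <- lapply(names(error_curves), function(nm) {
    d <- error_curves[[nm]]
    stopifnot(nrow(d) > 0)
    d <- d[order(d$pressure_parameter), ]
    i <- which.min(d$error)  # first minimum = smallest parameter on ties
    if (all(d$error == d$error[1]) && nrow(d) > 1)
      warning("flat error curve for ", nm, " mmHg: first point reported")
    else if (i == 1L || i == nrow(d))
      warning("error minimum at curve boundary for ", nm,
              " mmHg (no interior minimum)")
    data.frame(mmHg = as.numeric(nm),
               pressure_parameter = d$pressure_parameter[i],
               error = d$error[i])
  })
  do.call(rbind, rows)
}

#' Cubic simulation-pressure-to-mmHg map
#'
#' A degree-3 polynomial `y = a3 x^3 + a2 x^2 + a1 x + a0` mapping the
#' dimensionless simulation pressure parameter x to the experimental
#' insufflation pressure y in mmHg.
#'
#' @param a3,a2,a1,a0 Polynomial coefficients.
#' @param r_squared Fit diagnostic (optional).
#' @param residuals Fit residuals (optional).
#' @return A `pressure_map` object.
#' @export
pressure_map <- function(a3, a2, a1, a0, r_squared = NA_real_,
                         residuals = NULL) {
  coefs <- as.numeric(c(a3 = a3, a2 = a2, a1 = a1, a0 = a0))
  if (any(!is.finite(coefs))) stop("non-finite pressure map coefficients")
  structure(list(coefficients = setNames(coefs, c("a3", "a2", "a1", "a0")),
                 r_squared = r_squared, residuals = residuals),
            class = "pressure_map")
}

#' @export
print.pressure_map <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("pressure_map: y = %g x^3 + %g x^2 + %g x + %g (R^2 = %s)\n",
              co["a3"], co["a2"], co["a1"], co["a0"],
              ifelse(is.na(x$r_squared), "NA", signif(x$r_squared, 4))))
  invisible(x)
}

#' The published porcine pressure map
#'
#' The cubic calibration obtained on the porcine validation series
#' (minimum-voxel-error matches at 4, 8, 12 and 16 mmHg plus the (1, 0)
#' initial-configuration point): `y = 0.038 x^3 - 0.57 x^2 + 3.4 x - 2.9`.
#'
#' @return A [pressure_map()].
#' @export
default_pressure_map <- function() {
  pressure_map(0.038, -0.57, 3.4, -2.9, r_squared = 0.987)
}

#' Fit a cubic pressure map
#'
#' Unconstrained least-squares cubic through the matched
#' (pressure parameter, mmHg) points. When `anchor` is supplied the fit is
#' constrained to pass exactly through it (by basis substitution). The
#' default workflow fits unconstrained with the anchor included as an
#' ordinary data point, which is why the resulting polynomial need not
#' evaluate to exactly 0 mmHg at x = 1.
#'
#' @param points Data frame or matrix with columns x (pressure parameter)
#'   and y (mmHg); at least 4 rows (3 with an anchor).
#' @param anchor Optional `c(x0, y0)` the curve must pass through.
#' @return A [pressure_map()] with `r_squared` and `residuals` filled in.
#' @export
fit_pressure_map <- function(points, anchor = NULL) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("x", "y")
  x <- points$x
  y <- points$y
  if (is.null(anchor)) {
    if (length(x) < 4) stop("need at least 4 points for an unconstrained fit")
    fit <- lm(y ~ x + I(x^2) + I(x^3))
    co <- coef(fit)
    if (anyNA(co)) stop("rank-deficient cubic fit")
    pm <- pressure_map(co[4], co[3], co[2], co[1])
  } else {
    if (length(x) < 3) stop("need at least 3 points for an anchored fit")
    x0 <- anchor[1]
    y0 <- anchor[2]
    b1 <- x - x0
    b2 <- x^2 - x0^2
    b3 <- x^3 - x0^3
    dy <- y - y0
    fit <- lm(dy ~ 0 + b1 + b2 + b3)
    co <- coef(fit)
    if (anyNA(co)) stop("rank-deficient cubic fit")
    a0 <- y0 - co[1] * x0 - co[2] * x0^2 - co[3] * x0^3
    pm <- pressure_map(co[3], co[2], co[1], a0)
  }
  pred <- map_pressure(pm, x, warn = FALSE)
  res <- y - pred
  ss_tot <- sum((y - mean(y))^2)
  pm$r_squared <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  pm$residuals <- res
  pm
}

#' Evaluate a pressure map
#'
#' @param pm A [pressure_map()].
#' @param x Simulation pressure parameter(s); values outside the fitted
#'   range \[1, 15\] raise an extrapolation warning.
#' @param warn Emit the extrapolation warning (default TRUE).
#' @return Pressure(s) in mmHg (unrounded; the reporting convention is the
#'   nearest integer).
#' @export
map_pressure <- function(pm, x, warn = TRUE) {
  if (warn && any(x < 1 | x > 15))
    warning("pressure parameter outside the fitted range [1, 15]: ",
            "extrapolating")
  co <- pm$coefficients
  unname(co["a3"] * x^3 + co["a2"] * x^2 + co["a1"] * x + co["a0"])
}

#' Invert a pressure map
#'
#' Finds the simulation pressure parameter in \[1, 15\] at which the map
#' equals the given pressure, by sign-change bracketing and safeguarded
#' root refinement. Multiple roots in range raise an error listing them.
#'
#' @param pm A [pressure_map()].
#' @param y Target pressure in mmHg.
#' @param interval Search interval (default `c(1, 15)`).
#' @return The pressure parameter x with `map_pressure(pm, x) == y`.
#' @export
invert_pressure_map <- function(pm, y, interval = c(1, 15)) {
  f <- function(x) map_pressure(pm, x, warn = FALSE) - y
  xs <- seq(interval[1], interval[2], length.out = 2001)
  fs <- f(xs)
  hit <- which(abs(fs) < 1e-12)
  sign_change <- which(fs[-length(fs)] * fs[-1] < 0)
  roots <- c(xs[hit],
             vapply(sign_change, function(i)
               stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-10)$root,
               numeric(1)))
  roots <- sort(unique(round(roots, 9)))
  if (length(roots) == 0)
    stop("no root of the pressure map at ", y, " mmHg within [",
         interval[1], ", ", interval[2], "]")
  if (length(roots) > 1)
    stop("multiple roots at ", y, " mmHg: ",
         paste(signif(roots, 6), collapse = ", "))
  roots
}

#' Hausdorff validation report against reference meshes
#'
#' Per matched (simulated, reference) mesh pair, the mean and maximum
#' symmetric Hausdorff distance, as a validation table.
#'
#' @param sim_meshes,ref_meshes Lists of [triangle_mesh()]es of equal
#'   length, at original scale.
#' @param pressures Optional vector of pressures (mmHg) labelling the rows.
#' @param samples_per_area Passed to [hausdorff_distance()].
#' @param csv Optional path; when given the table is also written as CSV.
#' @return Data frame with `pressure`, `mean`, `max` (mm).
#' @export
validate_against_references <- function(sim_meshes, ref_meshes,
                                        pressures = NULL,
                                        samples_per_area = 1, csv = NULL) {
  if (length(sim_meshes) != length(ref_meshes))
    stop("sim and reference mesh lists have different lengths")
  if (is.null(pressures)) pressures <- seq_along(sim_meshes)
  rows <- lapply(seq_along(sim_meshes), function(i) {
    rep_ <- hausdorff_distance(sim_meshes[[i]], ref_meshes[[i]],
                               samples_per_area)
    data.frame(pressure = pressures[i], mean = rep_$mean, max = rep_$max)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}
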