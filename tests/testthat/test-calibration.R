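paper_cubic <- function(x) 0.038 * x^3 - 0.57 * x^2 + 3.4 * x - 2.9

test_that("cubic fit interpolates exact data to machine precision", {
  x <- c(1, 4, 7, 10, 13)
  pm <- fit_pressure_map(data.frame(x = x, y = paper_cubic(x)))
  expect_lt(max(abs(pm$residuals)), 1e-9)
  expect_equal(unname(pm$coefficients),
               c(0.038, -0.57, 3.4, -2.9), tolerance = 1e-9)
})

test_that("noisy cubic coefficients are recovered within three standard errors", {
  set.seed(2024)
  x <- seq(1, 15, length.out = 20)
  y <- paper_cubic(x) + rnorm(20, sd = 0.2)
  pm <- fit_pressure_map(data.frame(x = x, y = y))
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  se <- summary(fit)$coefficients[, "Std. Error"]
  est <- c(pm$coefficients[["a0"]], pm$coefficients[["a1"]],
           pm$coefficients[["a2"]], pm$coefficients[["a3"]])
  truth <- c(-2.9, 3.4, -0.57, 0.038)
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("anchored fit passes exactly through the anchor", {
  x <- c(2, 5, 8, 12)
  pm <- fit_pressure_map(data.frame(x = x, y = paper_cubic(x) + 0.1),
                         anchor = c(1, 0))
  expect_equal(map_pressure(pm, 1), 0, tolerance = 1e-10)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_pressure_map(data.frame(x = 1:3, y = 1:3)), "at least 4")
  expect_error(fit_pressure_map(data.frame(x = rep(2, 5), y = 1:5)),
               "rank-deficient")
})

test_that("the published map evaluates and inverts consistently", {
  pm <- default_pressure_map()
  expect_equal(map_pressure(pm, 10.5), 13.94725)
  expect_equal(map_pressure(pm, 1), -0.032)
  expect_warning(map_pressure(pm, 20), "outside")

  x0 <- invert_pressure_map(pm, 14)
  expect_equal(x0, 10.52, tolerance = 1e-2)
  for (x in c(1.5, 4.5, 8.5, 12)) {
    expect_lt(abs(invert_pressure_map(pm, map_pressure(pm, x)) - x), 1e-6)
  }
  expect_error(invert_pressure_map(pm, 1000), "no root")
  wavy <- pressure_map(1, -6, 11, -6)   # roots of y=0 at x = 1, 2, 3
  expect_error(invert_pressure_map(wavy, 0), "multiple roots")
})

test_that("match_pressures finds planted minima and flags degenerate curves", {
  curve <- function(centre, xs = seq(1, 15, 0.5))
    data.frame(pressure_parameter = xs, error = (xs - centre)^2 + 1)
  res <- match_pressures(list("4" = curve(3.5), "8" = curve(8.5),
                              "16" = curve(11)))
  expect_equal(res$pressure_parameter, c(3.5, 8.5, 11))
  expect_equal(res$mmHg, c(4, 8, 16))

  tie <- data.frame(pressure_parameter = c(1, 2, 3), error = c(5, 2, 2))
  expect_equal(match_pressures(list("8" = tie))$pressure_parameter, 2)

  mono <- data.frame(pressure_parameter = 1:5, error = 5:1)
  expect_warning(res <- match_pressures(list("8" = mono)), "boundary")
  expect_equal(res$pressure_parameter, 5)

  flat <- data.frame(pressure_parameter = 1:5, error = rep(2, 5))
  expect_warning(res <- match_pressures(list("8" = flat)), "flat")
  expect_equal(res$pressure_parameter, 1)
})

test_that("calibration aggregation matches a brute-force argmin oracle", {
  set.seed(31)
  grid <- expand.grid(subject = 1:3, cluster_stiffness = c(0.5, 0.6),
                      spring_stiffness = c(0.4, 0.5),
                      particle_radius = 2.7, pressure = seq(5, 8, 0.5))
  grid$error <- runif(nrow(grid), 1, 10)
  grid$converged <- TRUE
  # plant a clear winner
  win <- grid$cluster_stiffness == 0.6 & grid$spring_stiffness == 0.4
  grid$error[win] <- grid$error[win] / 20
  res <- pneumosim:::summarise_calibration(grid)

  # oracle: loop over parameter sets, average per-subject minima
  params <- unique(grid[, 2:4])
  oracle_best <- NULL
  oracle_val <- Inf
  for (i in seq_len(nrow(params))) {
    sel <- grid$cluster_stiffness == params$cluster_stiffness[i] &
      grid$spring_stiffness == params$spring_stiffness[i]
    v <- mean(tapply(grid$error[sel], grid$subject[sel], min))
    if (v < oracle_val) {
      oracle_val <- v
      oracle_best <- params[i, ]
    }
  }
  expect_equal(res$best$cluster_stiffness, oracle_best$cluster_stiffness)
  expect_equal(res$best$spring_stiffness, oracle_best$spring_stiffness)
  expect_equal(min(res$summary$avg_min_error), oracle_val)

  # a parameter set with any missing cell cannot win
  grid2 <- grid
  grid2$error[win][1] <- NA
  res2 <- pneumosim:::summarise_calibration(grid2)
  expect_false(res2$best$cluster_stiffness == 0.6 &&
                 res2$best$spring_stiffness == 0.4)

  # ties break towards the lexicographically smallest tuple
  grid3 <- grid
  grid3$error <- rep(1, nrow(grid3))
  res3 <- pneumosim:::summarise_calibration(grid3)
  expect_equal(res3$best$cluster_stiffness, 0.5)
  expect_equal(res3$best$spring_stiffness, 0.4)
})

test_that("grid search on a single grid point returns that point", {
  ph <- make_phantom(mini_phantom_spec())
  subject <- list(wall = ph$wall, viscera = ph$viscera, pneumo = ph$pneumo,
                  reference = ph$pneumo)
  g <- grid_spec(cluster_stiffness = 0.6, spring_stiffness = 0.5,
                 particle_radius = 2.7, pressure = 1)
  res <- run_grid_search(list(subject), g, experiment_config(max_steps = 50),
                         scale_factor = 1, seed = 1)
  expect_equal(res$best$cluster_stiffness, 0.6)
  expect_equal(res$per_subject$pressure, 1)
  expect_lt(res$per_subject$min_error, 0.1)   # kp = 1 leaves the mesh in place
})

test_that("validation report has one row per pair and zero for identical meshes", {
  s <- sphere_mesh(r = 10, subdivisions = 2)
  rep_ <- validate_against_references(list(s, s), list(s, s),
                                      pressures = c(4, 8),
                                      samples_per_area = 0.25)
  expect_identical(nrow(rep_), 2L)
  expect_equal(rep_$mean, c(0, 0))
  expect_equal(rep_$pressure, c(4, 8))
  expect_error(validate_against_references(list(s), list(s, s)),
               "different lengths")
})

test_that("the default grid spec covers the published calibration ranges", {
  g <- grid_spec()
  expect_equal(range(g$pressure), c(1, 15))
  expect_equal(length(g$pressure), 29)
  expect_equal(g$particle_radius, c(2.2, 2.7, 3.3))
  expect_equal(length(g$spring_stiffness), 10)
  expect_equal(length(g$cluster_stiffness), 5)
})
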