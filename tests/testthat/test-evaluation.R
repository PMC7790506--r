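test_that("trace RMSE matches hand computations and behaves as a metric", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 5, 5), c(2, 2, 2)), 3)            # constant difference
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  expect_error(rmse(1:3, 1:4), "equal length")

  set.seed(31)
  a <- rnorm(50); b <- rnorm(50); c <- rnorm(50)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_lte(rmse(a, c), rmse(a, b) + rmse(b, c) + 1e-12)
})

test_that("reconstruction RMSE maps score cubes against parameter maps", {
  cfg <- sim_config(2, noise = FALSE)
  sim <- make_test_cube(cfg, fix_delta_irf(), nx = 5, ny = 4, seed = 32)
  truth_maps <- list(tau = sim$tau, alpha = sim$alpha)

  # truth parameters on a noiseless cube: essentially exact reconstruction
  rep0 <- rmse_map(sim$cube, truth_maps, irf = NULL, offset = FALSE)
  expect_lt(rep0$median, 1e-6)

  # Poisson noise sets a strictly positive error floor
  cfg_n <- sim_config(2)
  set.seed(33)
  noisy <- flim_cube(array(rpois(length(sim$cube$data), sim$cube$data),
                           dim(sim$cube$data)), sim$cube$time)
  rep1 <- rmse_map(noisy, truth_maps, irf = NULL, offset = FALSE)
  expect_gt(rep1$median, rep0$median)
  expect_gt(rep1$median, 0.5)      # sqrt of Poisson variance at this scale

  # median is invariant to pixel ordering
  perm <- sample(20)
  M <- matrix(noisy$data, 20, 921)
  cube_p <- flim_cube(array(t(M[perm, ]), c(921, 5, 4)), noisy$time,
                      layout = "txy")
  maps_p <- list(tau = sim$tau[perm, ], alpha = sim$alpha[perm, ])
  rep_p <- rmse_map(cube_p, maps_p, irf = NULL, offset = FALSE)
  expect_equal(rep_p$median, rep1$median)
})

test_that("RMSE ratios compare two methods pixel by pixel", {
  mk <- function(eps) structure(list(per_trace = eps, median = median(eps),
                                     keep = rep(TRUE, length(eps)),
                                     method_label = "x"),
                                class = "flim_rmse_report")
  a <- mk(c(1, 2, 3, 4))
  expect_equal(rmse_ratio(a, a)$ratio, rep(1, 4))
  b <- mk(c(1, 2, 3, 4) / 2)
  r <- rmse_ratio(a, b)
  expect_equal(r$ratio, rep(2, 4))
  expect_equal(r$fraction_above_1, 1)

  z <- mk(c(1, 0, 3, 4))
  rz <- rmse_ratio(a, z)
  expect_equal(rz$n_excluded, 1L)
  expect_length(rz$ratio, 3)

  short <- mk(c(1, 2))
  expect_error(rmse_ratio(a, short), "different pixel sets")
})

test_that("recovery reports quantify bias and central error intervals", {
  set.seed(34)
  truth <- list(tau = cbind(runif(200, 0.2, 0.6), runif(200, 2, 4)),
                alpha = {
                  a <- matrix(runif(400), 200); a / rowSums(a)
                })

  # perfect prediction: zero bias, zero-width interval
  rec0 <- recovery_report(truth, truth)
  expect_equal(rec0$bias, rep(0, 4))
  expect_equal(rec0$ci_halfwidth, rep(0, 4))

  # constant +10% lifetime inflation collapses the interval at +10
  inflated <- list(tau = truth$tau * 1.10, alpha = truth$alpha)
  rec1 <- recovery_report(truth, inflated)
  tau_rows <- rec1$quantity == "tau"
  expect_equal(rec1$bias[tau_rows], rep(10, 2), tolerance = 1e-9)
  expect_equal(rec1$ci_lo[tau_rows], rep(10, 2), tolerance = 1e-9)
  expect_equal(rec1$ci_hi[tau_rows], rep(10, 2), tolerance = 1e-9)

  # abundance errors are reported in percentage points
  shifted <- list(tau = truth$tau,
                  alpha = truth$alpha + cbind(rep(0.05, 200), rep(-0.05, 200)))
  rec2 <- recovery_report(truth, shifted)
  expect_equal(rec2$bias[rec2$quantity == "alpha"], c(5, -5), tolerance = 1e-9)

  expect_error(recovery_report(truth, list(tau = truth$tau[, 1, drop = FALSE],
                                           alpha = truth$alpha)),
               "matching dimensions")
})

test_that("parameter maps round-trip through CSV", {
  cfg <- sim_config(2)
  sim <- make_test_cube(cfg, fix_irf(), nx = 4, ny = 4, seed = 35)
  train <- make_training_set(cfg, m = 60, seed = 36)
  maps <- predict_cube(train_bundle(train, num_trees = 60, seed = 37),
                       sim$cube, fix_irf())
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_maps(maps, path)
  back <- read_parameter_maps(path, 4, 4)
  expect_equal(back$tau_ps, maps$tau_ps, tolerance = 1e-9)
  expect_equal(back$alpha_pct, maps$alpha_pct, tolerance = 1e-9)
  expect_equal(back$mask$keep, maps$mask$keep)
})

test_that("percentile limits clip display outliers", {
  x <- c(rep(1, 998), 100, -50)
  lim <- percentile_limits(x)
  expect_lt(lim[2], 100)
  expect_gt(lim[1], -50)
  expect_equal(percentile_limits(1:1000, 0, 1), c(1, 1000))
})
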