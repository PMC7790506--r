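make_raw_cube <- function(nx = 3, ny = 2, p = 1024, seed = 1) {
  set.seed(seed)
  tx <- time_axis(p = p)
  cfg <- sim_config(2, time = tx)
  irf <- gaussian_irf(tx, center = 1.0)   # rise well after the first bins
  make_test_cube(cfg, irf, nx = nx, ny = ny, seed = seed)$cube
}

test_that("channel trimming keeps bins 40..960 and re-zeroes the axis", {
  cube <- make_raw_cube()
  trimmed <- trim_channels(cube, 40, 960)
  expect_equal(dim(trimmed$data)[3], 921)
  expect_equal(trimmed$time$p, 921L)
  expect_equal(trimmed$time$t[1], 0)
  expect_equal(trimmed$data[, , 1], cube$data[, , 40])

  # full-range trim is the identity apart from the time shift
  full <- trim_channels(cube, 1, 1024)
  expect_equal(full$data, cube$data)
  expect_equal(full$time$t, cube$time$t - cube$time$t[1])

  expect_error(trim_channels(cube, 0, 960), "trim bins")
  expect_error(trim_channels(cube, 900, 100), "trim bins")
})

test_that("offset subtraction averages the pre-rise window", {
  tx <- fix_time()
  # decay with an exactly dark pre-rise region (counting starts at bin 61)
  decay <- c(rep(0, 60), 150 * exp(-tx$t[seq_len(tx$p - 60)] / 2.5))

  # flat prefix of 5 before the rise is removed entirely
  shifted <- decay + 5
  out <- subtract_offset(shifted)
  rise <- which(shifted > 0.1 * max(shifted))[1]
  expect_equal(out[seq_len(rise - 1)], rep(0, rise - 1))
  expect_equal(attr(out, "offset"), 5, tolerance = 1e-9)

  # offset-free trace passes through (up to clipping of exact zeros)
  clean <- subtract_offset(decay)
  expect_equal(as.numeric(clean), pmax(decay - attr(clean, "offset"), 0))
  expect_lt(attr(clean, "offset"), 1e-9)

  # Poisson case: recovered offset within 3 SE of the true constant
  set.seed(6)
  noisy <- rpois(length(decay), decay + 7)
  outn <- subtract_offset(noisy)
  nwin <- which(noisy > 0.1 * max(noisy))[1] - 1
  expect_lt(abs(attr(outn, "offset") - 7), 3 * sqrt(7 / nwin) + 1e-9)

  # no pre-rise window: offset 0 with a warning
  expect_warning(out0 <- subtract_offset(c(100, 50, 25, 12, 6, 3)), "offset set to 0")
  expect_equal(attr(out0, "offset"), 0)
})

test_that("l2 normalization produces unit-norm traces", {
  v <- c(3, 4, rep(0, 919))
  expect_equal(l2_normalize(v)[1:2], c(0.6, 0.8))
  u <- l2_normalize(rnorm(100))
  expect_equal(l2_normalize(u), u)
  set.seed(7)
  M <- matrix(rexp(1000 * 30), 1000)
  expect_equal(sqrt(rowSums(l2_normalize(M)^2)), rep(1, 1000))
  expect_error(l2_normalize(numeric(10)), "all-zero")
})

test_that("pixel masking thresholds the per-pixel maximum count", {
  cfg <- sim_config(2, noise = FALSE)
  sim <- make_test_cube(cfg, fix_irf(), nx = 6, ny = 6, seed = 8)
  cube <- sim$cube

  expect_true(all(mask_pixels(cube, 0)$keep))

  dim8 <- flim_cube(array(8, c(4, 4, 921)), fix_time())
  expect_false(any(mask_pixels(dim8, 9)$keep))

  # zero out 10 chosen pixels -> exactly those are masked at threshold 9
  zeroed <- cube$data
  drop_idx <- cbind(c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4), c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  for (i in seq_len(nrow(drop_idx))) zeroed[drop_idx[i, 1], drop_idx[i, 2], ] <- 0
  mk <- mask_pixels(flim_cube(zeroed, cube$time), 9)
  expect_equal(sum(!mk$keep), 10L)
  expect_true(all(!mk$keep[drop_idx]))
})

test_that("the preprocessing pipeline yields unit-norm deconvolved traces", {
  cfg <- sim_config(2)
  sim <- make_test_cube(cfg, fix_irf(), nx = 4, ny = 3, seed = 9)
  pp <- preprocess_cube(sim$cube, fix_irf())
  expect_equal(dim(pp$traces), c(12, 921))
  expect_equal(sqrt(rowSums(pp$traces^2)), rep(1, 12))

  # single-pixel cube
  one <- flim_cube(array(sim$cube$data[1, 1, ], c(1, 1, 921)), fix_time())
  pp1 <- preprocess_cube(one, fix_irf())
  expect_equal(dim(pp1$traces), c(1, 921))

  # per-trace processing: permuting pixels permutes rows identically
  perm <- flim_cube(sim$cube$data[c(3, 1, 2, 4), , , drop = FALSE], fix_time())
  ppp <- preprocess_cube(perm, fix_irf(), basis = pp$basis)
  reord <- matrix(aperm(array(t(pp$traces), c(921, 4, 3)), c(2, 3, 1))[c(3, 1, 2, 4), , ],
                  12, 921)
  expect_equal(ppp$traces, reord, tolerance = 1e-10)

  # raw 1024-channel cubes are trimmed automatically
  raw <- make_raw_cube(nx = 2, ny = 2, seed = 10)
  irf_trim <- gaussian_irf(fix_time(), center = 1.0)
  ppr <- preprocess_cube(raw, irf_trim)
  expect_equal(ncol(ppr$traces), 921)
})
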