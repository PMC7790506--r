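test_that("generalized Laguerre recurrence matches closed forms", {
  x <- seq(0, 12, length.out = 7)
  expect_equal(laguerre_polynomial(0, 2, x), rep(1, 7))
  expect_equal(laguerre_polynomial(1, 2, 0), 3)            # alpha + 1 - x
  expect_equal(laguerre_polynomial(1, 2, x), 3 - x)

  # frozen values from symbolic differentiation of the Rodrigues form
  expect_equal(laguerre_polynomial(5, 2, 1.7), -2.80279225, tolerance = 1e-10)
  expect_equal(laguerre_polynomial(3, 2, 2.5), -95 / 48, tolerance = 1e-12)
  expect_equal(laguerre_polynomial(15, 2, 3.1), -3.0486451509784733,
               tolerance = 1e-10)

  # independent series oracle, all orders used by the default basis; x kept
  # where the alternating series is itself accurate to this precision
  set.seed(42)
  xs <- runif(50, 0, 4)
  for (n in 1:15) {
    got <- laguerre_polynomial(n, 2, xs)
    ref <- laguerre_series_oracle(n, 2, xs)
    expect_lt(max(abs(got - ref) / pmax(abs(ref), 1)), 1e-10)
  }

  expect_error(laguerre_polynomial(2, -1, 1), "alpha")
  expect_error(laguerre_polynomial(-1, 2, 1), "non-negative")
})

test_that("basis construction convolves each polynomial with the IRF", {
  b <- laguerre_basis(fix_time(), fix_delta_irf())
  expect_equal(b$L, b$B, tolerance = 1e-10)

  zero <- flim_irf(numeric(fix_time()$p), fix_time(), normalize = FALSE)
  bz <- laguerre_basis(fix_time(), zero)
  expect_equal(max(abs(bz$L)), 0)

  # full numerical rank for the default geometry
  expect_equal(qr(t(fix_basis()$B))$rank, 15L)
  expect_equal(qr(t(fix_basis()$L))$rank, 15L)
})

test_that("projection recovers exact coefficients and fits noiseless decays", {
  b <- fix_basis()
  set.seed(1)
  C0 <- matrix(rnorm(15, sd = 5), 1)
  tr <- C0 %*% b$L
  C <- lpd_project(tr, b, nonneg = FALSE)   # random coefficients: unphysical trace
  # the fitted trace is recovered exactly; the coefficients only up to the
  # basis conditioning (the convolved polynomials are nearly dependent)
  expect_lt(sqrt(sum((unclass(C) %*% b$L - tr)^2)) / sqrt(sum(tr^2)), 1e-10)
  expect_lt(max(abs(unclass(C) - C0)), 1e-5 * max(abs(C0)))

  expect_equal(max(abs(lpd_project(numeric(fix_time()$p), b))), 0)

  # noiseless two-component convolved decays reconstruct to < 1%
  tx <- fix_time()
  set.seed(2)
  taus <- cbind(runif(20, 0.05, 1.5), runif(20, 1.0, 7.0))
  alphas <- matrix(runif(40, 0.05, 1), 20); alphas <- alphas / rowSums(alphas)
  M <- t(sapply(seq_len(20), function(i)
    convolve_irf(pure_decay(component_params(taus[i, ], alphas[i, ]), tx, 150),
                 fix_irf())$counts))
  Cm <- lpd_project(M, b)
  rel <- attr(Cm, "diagnostics")$per_trace
  expect_lt(max(rel), 0.01)

  # scaling linearity (before normalization)
  one <- M[1, ]
  expect_equal(unclass(lpd_project(3 * one, b)), 3 * unclass(lpd_project(one, b)),
               tolerance = 1e-8)
})

test_that("deconvolution recovers the IRF-free decay", {
  b <- fix_basis()
  tx <- fix_time()

  # monoexponential tau = 2: deconvolved log-tail slope within 2% of -1/tau
  mono <- convolve_irf(pure_decay(component_params(2, 1), tx, 150), fix_irf())
  dec <- lpd_deconvolve(lpd_project(mono$counts, b), b)
  expect_equal(tail_lifetime(dec[1, ], tx, from = 3, to = 9), 2, tolerance = 0.02)

  # slow-component slope of a two-component decay
  duo <- convolve_irf(pure_decay(component_params(c(0.3, 2.5), c(0.5, 0.5)), tx, 150),
                      fix_irf())
  decd <- lpd_deconvolve(lpd_project(duo$counts, b), b)
  expect_equal(tail_lifetime(decd[1, ], tx, from = 5, to = 10), 2.5, tolerance = 0.02)

  # delta IRF: project + deconvolve is exact for traces inside the span
  bd <- laguerre_basis(tx, fix_delta_irf())
  inspan <- matrix(rnorm(15), 1) %*% bd$B
  expect_equal(lpd_deconvolve(lpd_project(inspan, bd, nonneg = FALSE), bd),
               inspan, tolerance = 1e-8)
})

test_that("round trip through span(L) and the fit-quality gate hold", {
  b <- fix_basis()
  set.seed(3)
  C0 <- matrix(rnorm(45, sd = 3), 3)
  traces <- C0 %*% b$L
  dec <- lpd_deconvolve(lpd_project(traces, b, nonneg = FALSE), b)
  back <- t(apply(dec, 1, function(x) convolve_irf(x, fix_irf())$counts))
  expect_lt(max(abs(back - traces)) / max(abs(traces)), 1e-6)

  # fit-quality gate on a noisy synthetic batch: mean-trace error < 2%
  tx <- fix_time()
  cfg <- sim_config(2)
  sim <- make_test_cube(cfg, fix_irf(), nx = 10, ny = 10, seed = 4)
  M <- matrix(sim$cube$data, 100, 921)
  Cm <- lpd_project(M, b)
  q <- lpd_fit_quality(M, b, Cm)
  expect_true(q$ok)
  expect_lt(q$mean_trace_error, 0.02)
  expect_length(q$per_trace, 100)
})

test_that("non-negativity refinement keeps fitted traces physical", {
  b <- fix_basis()
  tx <- fix_time()
  set.seed(5)
  mu <- convolve_irf(pure_decay(component_params(c(0.2, 3), c(0.7, 0.3)), tx, 150),
                     fix_irf())$counts
  noisy <- t(matrix(rpois(length(mu) * 20, rep(mu, 20)), length(mu), 20))
  C <- lpd_project(noisy, b, nonneg = TRUE, tol = 1e-3)
  fit <- unclass(C) %*% b$L
  peaks <- apply(abs(fit), 1, max)
  expect_true(all(apply(fit, 1, min) >= -10e-3 * peaks))
  # unconstrained regime is linear
  Cu <- lpd_project(noisy, b, nonneg = FALSE)
  expect_equal(unclass(lpd_project(2 * noisy, b, nonneg = FALSE)),
               2 * unclass(Cu), tolerance = 1e-8)
})
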