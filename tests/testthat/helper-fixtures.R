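# Shared fixtures; everything generated in code, cached per test run.

.fix <- new.env(parent = emptyenv())

fix_time <- function() {
  if (is.null(.fix$time)) .fix$time <- time_axis()
  .fix$time
}

fix_irf <- function() {
  if (is.null(.fix$irf)) .fix$irf <- gaussian_irf(fix_time())
  .fix$irf
}

# delta kernel on the default axis (identity under causal convolution)
fix_delta_irf <- function() {
  if (is.null(.fix$delta)) {
    r <- numeric(fix_time()$p); r[1] <- 1
    .fix$delta <- flim_irf(r, fix_time())
  }
  .fix$delta
}

fix_basis <- function() {
  if (is.null(.fix$basis)) .fix$basis <- laguerre_basis(fix_time(), fix_irf())
  .fix$basis
}

# independent closed-form oracle for the generalized Laguerre polynomial:
# finite series sum_k (-1)^k choose(n + a, n - k) x^k / k!, summed with
# Neumaier compensation (the alternating series cancels heavily)
laguerre_series_oracle <- function(n, a, x) {
  vapply(x, function(xi) {
    s <- 0; comp <- 0
    for (k in 0:n) {
      term <- (-1)^k * choose(n + a, n - k) * xi^k / factorial(k)
      t2 <- s + term
      comp <- comp + if (abs(s) >= abs(term)) (s - t2) + term else (term - t2) + s
      s <- t2
    }
    s + comp
  }, numeric(1))
}

# log-linear tail slope -> lifetime estimate, over a time window (ns)
tail_lifetime <- function(counts, time, from = 3, to = 9) {
  t <- time$t
  sel <- t >= from & t <= to & counts > 0
  -1 / unname(stats::coef(stats::lm(log(counts[sel]) ~ t[sel]))[2])
}
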