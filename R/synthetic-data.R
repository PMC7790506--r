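#' Sample ground-truth decay parameters
#'
#' Draws lifetimes uniformly from each component's range and abundances
#' uniformly from their ranges followed by unit-sum rescaling. Components are
#' sorted ascending by lifetime within every draw, so "component i" has a
#' consistent meaning across traces even when ranges overlap (the regression
#' targets would otherwise be ill-defined).
#'
#' @param config A [sim_config()].
#' @param n Number of parameter sets to draw.
#' @param seed Optional integer seed.
#' @return List with `tau` and `alpha`, each an `n x N` matrix (unit-sum rows
#'   for `alpha`).
#' @export
sample_params <- function(config, n = 1, seed = NULL) {
  stopifnot(inherits(config, "flim_sim_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_components
  tau <- sapply(seq_len(N), function(i)
    stats::runif(n, config$tau_ranges[i, 1], config$tau_ranges[i, 2]))
  alpha <- sapply(seq_len(N), function(i)
    stats::runif(n, config$alpha_ranges[i, 1], config$alpha_ranges[i, 2]))
  tau <- matrix(tau, n, N); alpha <- matrix(alpha, n, N)
  s <- rowSums(alpha)
  if (any(s <= 0)) stop("drew an all-zero abundance vector; widen alpha_ranges")
  alpha <- alpha / s
  if (N > 1) {
    ord <- t(apply(tau, 1, order))
    idx <- cbind(rep(seq_len(n), N), as.vector(ord))
    tau <- matrix(tau[idx], n, N)
    alpha <- matrix(alpha[idx], n, N)
  }
  list(tau = tau, alpha = alpha)
}

## n x p matrix of noiseless decays for parameter matrices (rows = traces)
.decay_matrix <- function(tau, alpha, time, peak_scale) {
  n <- nrow(tau); p <- time$p
  M <- matrix(0, n, p)
  for (i in seq_len(ncol(tau)))
    M <- M + alpha[, i] * exp(-outer(1 / tau[, i], time$t))
  peak_scale * M
}

#' Simulate a training set of IRF-free decay traces
#'
#' Generates `m` pure multi-exponential decays (no IRF convolution - the
#' trained models stay independent of the measurement system), adds Poisson
#' noise when configured, and l2-normalizes each trace exactly as the
#' deconvolved test traces are normalized, so training and prediction share
#' one feature space.
#'
#' @param config A [sim_config()].
#' @param m Number of training traces (default 3000).
#' @param seed Integer seed.
#' @return An object of class `flim_training_set`: list with `traces`
#'   (`m x p` matrix, unit l2 norm rows), `tau`, `alpha` (`m x N` truth
#'   matrices, lifetimes ascending per row) and `config`.
#' @export
make_training_set <- function(config, m = 3000, seed = NULL) {
  stopifnot(inherits(config, "flim_sim_config"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  pars <- sample_params(config, m)
  M <- .decay_matrix(pars$tau, pars$alpha, config$time, config$peak_scale)
  if (config$noise)
    M <- matrix(stats::rpois(length(M), M), nrow(M), ncol(M))
  structure(list(traces = l2_normalize(M), tau = pars$tau, alpha = pars$alpha,
                 config = config),
            class = "flim_training_set")
}

#' @export
print.flim_training_set <- function(x, ...) {
  cat(sprintf("<flim_training_set> %d traces x %d channels, N = %d\n",
              nrow(x$traces), ncol(x$traces), x$config$n_components))
  invisible(x)
}

#' Simulate a FLIM test cube with known ground truth
#'
#' Draws per-pixel parameters, convolves the noiseless decays with the IRF,
#' adds Poisson noise when configured, and returns the cube together with its
#' per-pixel truth maps.
#'
#' @param config A [sim_config()].
#' @param irf A [flim_irf()] on `config$time`.
#' @param nx,ny Spatial dimensions (default 128 x 128).
#' @param seed Integer seed.
#' @return An object of class `flim_sim_cube`: list with `cube` (a
#'   [flim_cube()]), `tau`, `alpha` (`(nx*ny) x N` truth matrices in pixel
#'   column-major order), `config` and `irf`.
#' @export
make_test_cube <- function(config, irf, nx = 128, ny = 128, seed = NULL) {
  stopifnot(inherits(config, "flim_sim_config"), inherits(irf, "flim_irf"),
            nx >= 1, ny >= 1)
  if (irf$time$p != config$time$p || max(abs(irf$time$t - config$time$t)) > 1e-9)
    stop("IRF time axis does not match the simulation time axis")
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(nx) * as.integer(ny)
  pars <- sample_params(config, m)
  M <- .decay_matrix(pars$tau, pars$alpha, config$time, config$peak_scale)
  M <- .convolve_rows(M, irf$r)
  M[M < 0] <- 0
  if (config$noise)
    M <- matrix(stats::rpois(length(M), M), nrow(M), ncol(M))
  cube <- flim_cube(array(t(M), dim = c(config$time$p, nx, ny)),
                    config$time, layout = "txy")
  structure(list(cube = cube, tau = pars$tau, alpha = pars$alpha,
                 config = config, irf = irf),
            class = "flim_sim_cube")
}

#' @export
print.flim_sim_cube <- function(x, ...) {
  d <- dim(x$cube$data)
  cat(sprintf("<flim_sim_cube> %d x %d pixels x %d channels, N = %d\n",
              d[1], d[2], d[3], x$config$n_components))
  invisible(x)
}
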