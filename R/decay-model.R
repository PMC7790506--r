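#' Multi-exponential component parameters
#'
#' Lifetimes and fractional abundances of an N-component fluorescence decay.
#' Abundances can optionally be rescaled to unit sum, the convention used
#' throughout the estimation pipeline.
#'
#' @param tau Vector of N lifetimes in ns, all positive.
#' @param alpha Vector of N abundances (non-negative fractions).
#' @param rescale Rescale `alpha` to unit sum.
#' @return An object of class `flim_params`: list with `tau`, `alpha`, `n`.
#' @examples
#' component_params(c(0.3, 2.5), c(1, 1), rescale = TRUE)
#' @export
component_params <- function(tau, alpha, rescale = FALSE) {
  tau <- as.numeric(tau); alpha <- as.numeric(alpha)
  if (length(tau) != length(alpha)) stop("tau and alpha must have equal length")
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("lifetimes must be positive")
  if (any(!is.finite(alpha)) || any(alpha < 0)) stop("abundances must be non-negative")
  if (rescale) {
    s <- sum(alpha)
    if (s <= 0) stop("cannot rescale abundances with zero sum")
    alpha <- alpha / s
  }
  structure(list(tau = tau, alpha = alpha, n = length(tau)), class = "flim_params")
}

#' @export
print.flim_params <- function(x, ...) {
  cat(sprintf("<flim_params> N = %d\n  tau   (ns): %s\n  alpha     : %s\n",
              x$n, paste(signif(x$tau, 4), collapse = ", "),
              paste(signif(x$alpha, 4), collapse = ", ")))
  invisible(x)
}

#' Decay trace container
#'
#' @param counts Photon counts per channel (may be non-integer after
#'   preprocessing); raw counts must be non-negative.
#' @param time A [time_axis()].
#' @return An object of class `flim_trace`: list with `counts` and `time`.
#' @export
decay_trace <- function(counts, time) {
  time <- .as_time_axis(time)
  counts <- as.numeric(counts)
  if (length(counts) != time$p) stop("counts length does not match the time axis")
  structure(list(counts = counts, time = time), class = "flim_trace")
}

.trace_counts <- function(x) if (inherits(x, "flim_trace")) x$counts else as.numeric(x)

#' Noiseless multi-exponential decay
#'
#' Evaluates `peak_scale * sum_i alpha_i * exp(-t / tau_i)` on the time axis:
#' the IRF-free forward model used both for training-data simulation and as
#' the deconvolved target shape.
#'
#' @param params A [component_params()].
#' @param time A [time_axis()].
#' @param peak_scale Photon-count scale; with unit-sum abundances this is the
#'   count in the first channel (t = 0). Default 150.
#' @return A [decay_trace()].
#' @examples
#' tr <- pure_decay(component_params(2, 1), time_axis(), peak_scale = 150)
#' tr$counts[1]   # 150 at t = 0
#' @export
pure_decay <- function(params, time, peak_scale = 150) {
  stopifnot(inherits(params, "flim_params"), peak_scale > 0)
  time <- .as_time_axis(time)
  counts <- peak_scale * drop(exp(-outer(time$t, 1 / params$tau)) %*% params$alpha)
  decay_trace(counts, time)
}

## Causal discrete convolution truncated to the trace length:
## out[k] = sum_{j <= k} r[k - j + 1] * x[j].
.convolve_causal <- function(x, r) {
  n <- length(x)
  stopifnot(length(r) == n)
  out <- stats::convolve(x, rev(r), type = "open")[seq_len(n)]
  ## FFT round-off can leave tiny negatives on zero stretches
  out[abs(out) < 1e-12 * max(abs(out), 1)] <- 0
  out
}

## Row-wise causal convolution of a trace matrix with one kernel, FFT-based,
## processed in column blocks to bound memory.
.convolve_rows <- function(M, r, block = 2048L) {
  m <- nrow(M); p <- ncol(M)
  stopifnot(length(r) == p)
  N <- stats::nextn(2L * p, 2)
  R <- stats::fft(c(r, rep(0, N - p)))
  out <- matrix(0, m, p)
  for (i0 in seq(1L, m, by = block)) {
    i1 <- min(i0 + block - 1L, m)
    X <- rbind(t(M[i0:i1, , drop = FALSE]), matrix(0, N - p, i1 - i0 + 1L))
    Y <- Re(stats::mvfft(stats::mvfft(X) * R, inverse = TRUE)) / N
    out[i0:i1, ] <- t(Y[seq_len(p), , drop = FALSE])
  }
  out[abs(out) < 1e-12 * max(abs(out), 1)] <- 0
  out
}

#' Convolve a decay trace with the IRF
#'
#' Discrete causal convolution truncated to the trace support,
#' `out[k] = sum_{j<=k} r[k-j] * decay[j]`. Because the IRF is stored with
#' unit sum, the convolved trace keeps the amplitude scale of the input.
#'
#' @param decay A [decay_trace()] (or numeric vector on the IRF's axis).
#' @param irf A [flim_irf()] on the same time axis.
#' @return A [decay_trace()].
#' @export
convolve_irf <- function(decay, irf) {
  stopifnot(inherits(irf, "flim_irf"))
  x <- .trace_counts(decay)
  if (length(x) != irf$time$p) stop("decay and IRF lengths differ")
  decay_trace(.convolve_causal(x, irf$r), irf$time)
}

#' Add Poisson photon-counting noise
#'
#' Replaces every channel by a Poisson draw with mean equal to the noiseless
#' count, emulating TCSPC shot noise.
#'
#' @param decay A [decay_trace()] or numeric vector of non-negative means.
#' @param seed Optional integer seed for reproducibility.
#' @return Same type as the input, with integer counts.
#' @export
add_poisson_noise <- function(decay, seed = NULL) {
  x <- .trace_counts(decay)
  if (any(x < 0)) stop("Poisson means must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  y <- stats::rpois(length(x), x)
  if (inherits(decay, "flim_trace")) decay_trace(y, decay$time) else y
}

#' Reconstruct a decay trace from estimated parameters
#'
#' Noiseless forward evaluation (multi-exponential decay convolved with the
#' IRF) used for reconstruction-RMSE scoring. The estimated quantities carry
#' no absolute intensity, so an overall amplitude is fitted by least squares
#' against `scale_to` when supplied.
#'
#' @param params A [component_params()] (estimated or true).
#' @param irf A [flim_irf()]; `NULL` for an unconvolved (delta-IRF)
#'   reconstruction.
#' @param time A [time_axis()]; defaults to the IRF's axis.
#' @param scale Fixed amplitude; ignored when `scale_to` is given.
#' @param scale_to Optional measured trace (vector or [decay_trace()]) to
#'   which the reconstruction amplitude is fitted by least squares.
#' @return A [decay_trace()].
#' @export
reconstruct <- function(params, irf = NULL, time = NULL, scale = 150,
                        scale_to = NULL) {
  if (is.null(time)) {
    if (is.null(irf)) stop("either irf or time must be given")
    time <- irf$time
  }
  time <- .as_time_axis(time)
  base <- pure_decay(params, time, peak_scale = 1)
  rec <- if (is.null(irf)) base$counts else .convolve_causal(base$counts, irf$r)
  if (!is.null(scale_to)) {
    y <- .trace_counts(scale_to)
    denom <- sum(rec^2)
    scale <- if (denom > 0) sum(rec * y) / denom else 0
  }
  decay_trace(scale * rec, time)
}
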