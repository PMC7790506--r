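#' Simulation configuration
#'
#' Describes the conditions under which synthetic decay traces are generated:
#' number of exponential components, per-component lifetime and (pre-rescale)
#' abundance ranges, photon-count scale and Poisson noise.
#'
#' Default lifetime ranges cover biological autofluorophores (lifetimes up to
#' 7 ns, e.g. free vs protein-bound NAD(P)H) with deliberately broad and
#' partly overlapping per-component ranges, so one trained model generalizes
#' across samples:
#' * two components: tau1 in \[0.05, 1.5\], tau2 in \[1.0, 7.0\] ns
#' * three components: tau1 in \[0.05, 1.0\], tau2 in \[0.8, 4.0\],
#'   tau3 in \[3.0, 7.0\] ns
#' Abundances are drawn uniformly on \[0.05, 1\] per component and rescaled to
#' unit sum.
#'
#' @param n_components Number of exponential components N (>= 1).
#' @param tau_ranges N x 2 matrix (or list of length-2 vectors) of lifetime
#'   ranges in ns; `NULL` for the defaults above (N <= 3).
#' @param alpha_ranges N x 2 matrix of abundance ranges before unit-sum
#'   rescaling; default all \[0.05, 1\].
#' @param peak_scale Photon-count scale (default 150, i.e. a peak of about
#'   150 counts for unit-sum abundances).
#' @param noise Add Poisson noise (default `TRUE`).
#' @param time A [time_axis()]; default 921 channels of width 12.5/1024 ns.
#' @return An object of class `flim_sim_config`.
#' @export
sim_config <- function(n_components = 2, tau_ranges = NULL, alpha_ranges = NULL,
                       peak_scale = 150, noise = TRUE, time = time_axis()) {
  n <- as.integer(n_components)
  stopifnot(n >= 1, peak_scale > 0)
  if (is.null(tau_ranges)) {
    tau_ranges <- switch(as.character(n),
      "1" = rbind(c(0.05, 7.0)),
      "2" = rbind(c(0.05, 1.5), c(1.0, 7.0)),
      "3" = rbind(c(0.05, 1.0), c(0.8, 4.0), c(3.0, 7.0)),
      stop("no default lifetime ranges for N > 3; supply tau_ranges"))
  }
  tau_ranges <- .as_ranges(tau_ranges, n, "tau_ranges")
  if (any(tau_ranges <= 0)) stop("lifetime ranges must be positive")
  if (is.null(alpha_ranges)) alpha_ranges <- matrix(rep(c(0.05, 1), each = n), n, 2)
  alpha_ranges <- .as_ranges(alpha_ranges, n, "alpha_ranges")
  if (any(alpha_ranges < 0)) stop("abundance ranges must be non-negative")
  time <- .as_time_axis(time)
  structure(list(n_components = n, tau_ranges = tau_ranges,
                 alpha_ranges = alpha_ranges, peak_scale = peak_scale,
                 noise = isTRUE(noise), time = time),
            class = "flim_sim_config")
}

.as_ranges <- function(x, n, what) {
  if (is.list(x)) x <- do.call(rbind, x)
  x <- matrix(as.numeric(x), ncol = 2)
  if (nrow(x) != n) stop(sprintf("%s must have one row per component", what))
  if (any(x[, 1] > x[, 2])) stop(sprintf("%s must satisfy low <= high", what))
  colnames(x) <- c("low", "high")
  x
}

#' @export
print.flim_sim_config <- function(x, ...) {
  cat(sprintf("<flim_sim_config> N = %d, peak_scale = %g, noise = %s\n",
              x$n_components, x$peak_scale, x$noise))
  for (i in seq_len(x$n_components))
    cat(sprintf("  component %d: tau [%g, %g] ns, alpha [%g, %g]\n", i,
                x$tau_ranges[i, 1], x$tau_ranges[i, 2],
                x$alpha_ranges[i, 1], x$alpha_ranges[i, 2]))
  print(x$time)
  invisible(x)
}
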