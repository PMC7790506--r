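#' Root-mean-square error between two traces
#'
#' `sqrt(mean((I - Ihat)^2))` over channels, on raw-count scale.
#'
#' @param measured,reconstructed Equal-length numeric vectors or
#'   [decay_trace()] objects.
#' @return Non-negative scalar.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))   # sqrt(4/3)
#' @export
rmse <- function(measured, reconstructed) {
  a <- .trace_counts(measured); b <- .trace_counts(reconstructed)
  if (length(a) != length(b)) stop("traces must have equal length")
  sqrt(mean((a - b)^2))
}

#' Per-pixel reconstruction RMSE for a cube
#'
#' Reconstructs every kept pixel's decay from its estimated (or true)
#' parameters - noiseless multi-exponential decay convolved with the IRF,
#' amplitude fitted per pixel by least squares - and scores it against the
#' trimmed, offset-subtracted measured trace.
#'
#' @param cube A [flim_cube()].
#' @param maps A [predict_cube()] result (`flim_maps`), or a list with `tau`
#'   (ns) and `alpha` (fractions) matrices over kept pixels.
#' @param irf A [flim_irf()] on the trimmed axis; `NULL` for delta IRF.
#' @param trim,offset As in [preprocess_cube()].
#' @param method_label Free-text label stored in the report.
#' @return An object of class `flim_rmse_report`: list with `per_trace`,
#'   `median`, `keep` (logical vector over pixels) and `method_label`.
#' @export
rmse_map <- function(cube, maps, irf = NULL, trim = "auto", offset = TRUE,
                     method_label = "ML") {
  stopifnot(inherits(cube, "flim_cube"))
  if (identical(trim, "auto"))
    trim <- if (cube$time$p == 1024L) c(40, 960) else NULL
  if (!is.null(trim)) cube <- trim_channels(cube, trim[1], trim[2])
  time <- cube$time
  if (inherits(maps, "flim_maps")) {
    keep <- as.vector(maps$mask$keep)
    N <- maps$n_components
    tau <- sapply(seq_len(N), function(i) as.vector(maps$tau_ps[, , i])[keep]) / 1000
    alpha <- sapply(seq_len(N), function(i) as.vector(maps$alpha_pct[, , i])[keep]) / 100
    tau <- matrix(tau, sum(keep)); alpha <- matrix(alpha, sum(keep))
  } else {
    tau <- as.matrix(maps$tau); alpha <- as.matrix(maps$alpha)
    keep <- if (!is.null(maps$keep)) as.logical(maps$keep)
            else rep(TRUE, prod(dim(cube$data)[1:2]))
  }
  M <- .cube_traces(cube)[keep, , drop = FALSE]
  if (nrow(M) != nrow(tau)) stop("parameter maps do not match the kept pixel set")
  if (offset) M <- subtract_offset(M)
  R <- .decay_matrix(tau, alpha, time, 1)
  if (!is.null(irf)) {
    stopifnot(inherits(irf, "flim_irf"))
    R <- .convolve_rows(R, irf$r)
  }
  s <- rowSums(R * M) / pmax(rowSums(R^2), .Machine$double.eps)
  eps <- sqrt(rowMeans((M - s * R)^2))
  structure(list(per_trace = eps, median = stats::median(eps), keep = keep,
                 method_label = method_label),
            class = "flim_rmse_report")
}

#' @export
print.flim_rmse_report <- function(x, ...) {
  cat(sprintf("<flim_rmse_report> %s: %d traces, median RMSE = %.4g\n",
              x$method_label, length(x$per_trace), x$median))
  invisible(x)
}

#' Per-trace RMSE ratio between two methods
#'
#' Element-wise `eps_a / eps_b` over the shared pixel set; the fraction of
#' ratios above 1 summarizes which method reconstructs better. Zero
#' denominators are excluded and counted.
#'
#' @param report_a,report_b Two [rmse_map()] reports on the same pixels.
#' @return List with `ratio`, `fraction_above_1`, `n_excluded` and labels.
#' @export
rmse_ratio <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "flim_rmse_report"),
            inherits(report_b, "flim_rmse_report"))
  if (length(report_a$per_trace) != length(report_b$per_trace) ||
      !identical(report_a$keep, report_b$keep))
    stop("reports cover different pixel sets")
  ok <- report_b$per_trace > 0
  ratio <- report_a$per_trace[ok] / report_b$per_trace[ok]
  list(ratio = ratio,
       fraction_above_1 = mean(ratio > 1),
       n_excluded = sum(!ok),
       labels = c(report_a$method_label, report_b$method_label))
}

#' Parameter-recovery report against known ground truth
#'
#' For simulated data with known per-trace parameters: per quantity, the
#' bias (mean error) and the central interval of the error distribution.
#' Lifetime errors are expressed relative to the true lifetime in percent;
#' abundance errors in percentage points of the unit-sum abundance. "CI"
#' here means the central `level` interval of the empirical error
#' distribution (default 95%); the level is a parameter because boxplot-style
#' summaries of the same errors read off narrower spreads.
#'
#' @param truth,predicted Lists with `tau` and `alpha` matrices (`m x N`,
#'   matched rows), e.g. a [make_test_cube()]'s truth and a
#'   [predict.flim_bundle()] result.
#' @param level Central interval probability.
#' @return An object of class `flim_recovery_report`: a data.frame with one
#'   row per quantity (columns `quantity`, `component`, `unit`, `bias`,
#'   `ci_lo`, `ci_hi`, `ci_halfwidth`), plus attribute `"errors"` holding the
#'   per-trace error vectors.
#' @export
recovery_report <- function(truth, predicted, level = 0.95) {
  tt <- as.matrix(truth$tau); ta <- as.matrix(truth$alpha)
  pt <- as.matrix(predicted$tau); pa <- as.matrix(predicted$alpha)
  if (!all(dim(tt) == dim(pt)) || !all(dim(ta) == dim(pa)))
    stop("truth and predicted must have matching dimensions")
  N <- ncol(tt)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- list(); errs <- list()
  for (i in seq_len(N)) {
    e <- (pt[, i] - tt[, i]) / tt[, i] * 100
    q <- stats::quantile(e, qs, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "tau", component = i, unit = "% of true",
      bias = mean(e), ci_lo = q[1], ci_hi = q[2],
      ci_halfwidth = diff(q) / 2)
    errs[[sprintf("tau%d", i)]] <- e
  }
  for (i in seq_len(N)) {
    e <- (pa[, i] - ta[, i]) * 100
    q <- stats::quantile(e, qs, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "alpha", component = i, unit = "percentage points",
      bias = mean(e), ci_lo = q[1], ci_hi = q[2],
      ci_halfwidth = diff(q) / 2)
    errs[[sprintf("alpha%d", i)]] <- e
  }
  out <- do.call(rbind, rows)
  attr(out, "errors") <- errs
  attr(out, "level") <- level
  class(out) <- c("flim_recovery_report", class(out))
  out
}

#' Align simulated-cube truth with predicted maps
#'
#' Convenience extractor: returns matched `truth` and `predicted` lists over
#' the kept pixels of a simulated cube, ready for [recovery_report()].
#'
#' @param sim A [make_test_cube()] result.
#' @param maps The [predict_cube()] result for `sim$cube`.
#' @return List with `truth` and `predicted` (each `tau` in ns / `alpha`
#'   fractions over kept pixels).
#' @export
align_truth <- function(sim, maps) {
  stopifnot(inherits(sim, "flim_sim_cube"), inherits(maps, "flim_maps"))
  keep <- as.vector(maps$mask$keep)
  N <- maps$n_components
  pt <- sapply(seq_len(N), function(i) as.vector(maps$tau_ps[, , i])[keep]) / 1000
  pa <- sapply(seq_len(N), function(i) as.vector(maps$alpha_pct[, , i])[keep]) / 100
  list(truth = list(tau = sim$tau[keep, seq_len(N), drop = FALSE],
                    alpha = sim$alpha[keep, seq_len(N), drop = FALSE]),
       predicted = list(tau = matrix(pt, sum(keep)),
                        alpha = matrix(pa, sum(keep))))
}

#' Import externally produced parameter maps
#'
#' Reads a CSV with columns `x`, `y`, `tau_1..tau_N` (ps) and
#' `alpha_1..alpha_N` (percent), e.g. maps exported from a commercial fitting
#' package, for comparison via [rmse_map()] / [rmse_ratio()].
#'
#' @param path CSV path.
#' @param nx,ny Cube spatial dimensions the coordinates refer to.
#' @return A `flim_maps` object (pixels absent from the file are masked).
#' @export
read_parameter_maps <- function(path, nx, ny) {
  tab <- utils::read.csv(path)
  tau_cols <- grep("^tau_\\d+$", names(tab), value = TRUE)
  alpha_cols <- grep("^alpha_\\d+$", names(tab), value = TRUE)
  if (!all(c("x", "y") %in% names(tab)) || !length(tau_cols) ||
      length(tau_cols) != length(alpha_cols))
    stop("expected columns x, y, tau_1..tau_N, alpha_1..alpha_N")
  N <- length(tau_cols)
  keep <- matrix(FALSE, nx, ny)
  idx <- cbind(tab$x, tab$y)
  if (any(idx < 1) || any(idx[, 1] > nx) || any(idx[, 2] > ny))
    stop("pixel coordinates outside the cube dimensions")
  keep[idx] <- TRUE
  tau <- array(NA_real_, c(nx, ny, N)); alpha <- array(NA_real_, c(nx, ny, N))
  for (i in seq_len(N)) {
    m <- matrix(NA_real_, nx, ny); m[idx] <- tab[[tau_cols[i]]]; tau[, , i] <- m
    m <- matrix(NA_real_, nx, ny); m[idx] <- tab[[alpha_cols[i]]]; alpha[, , i] <- m
  }
  structure(list(tau_ps = tau, alpha_pct = alpha,
                 mask = structure(list(keep = keep, threshold = NA_real_),
                                  class = "flim_mask"),
                 n_components = N, diagnostics = NULL),
            class = "flim_maps")
}

#' Write parameter maps to CSV
#'
#' Inverse of [read_parameter_maps()]: kept pixels only, lifetimes in ps and
#' abundances in percent.
#'
#' @param maps A `flim_maps`.
#' @param path Output CSV path.
#' @export
write_parameter_maps <- function(maps, path) {
  stopifnot(inherits(maps, "flim_maps"))
  keep <- which(maps$mask$keep, arr.ind = TRUE)
  N <- maps$n_components
  out <- data.frame(x = keep[, 1], y = keep[, 2])
  for (i in seq_len(N)) out[[sprintf("tau_%d", i)]] <- maps$tau_ps[, , i][keep]
  for (i in seq_len(N)) out[[sprintf("alpha_%d", i)]] <- maps$alpha_pct[, , i][keep]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Percentile color limits
#'
#' Robust display limits for false-color maps: the 0.001 and 0.999 quantiles
#' by default, so a handful of outlier pixels cannot flatten the contrast.
#'
#' @param x Numeric values (NAs ignored).
#' @param lo,hi Lower/upper quantile probabilities.
#' @return Length-2 numeric vector.
#' @export
percentile_limits <- function(x, lo = 0.001, hi = 0.999) {
  stats::quantile(x, c(lo, hi), na.rm = TRUE, names = FALSE)
}

#' Display a parameter map
#'
#' False-color image of one quantity with percentile-clipped limits; masked
#' pixels render as black.
#'
#' @param maps A `flim_maps`.
#' @param quantity `"tau"` or `"alpha"`.
#' @param component Component index.
#' @param ... Passed to [graphics::image()].
#' @export
plot_map <- function(maps, quantity = c("tau", "alpha"), component = 1, ...) {
  quantity <- match.arg(quantity)
  z <- if (quantity == "tau") maps$tau_ps[, , component]
       else maps$alpha_pct[, , component]
  lim <- percentile_limits(z)
  z2 <- pmin(pmax(z, lim[1]), lim[2])
  graphics::image(z2, zlim = lim, useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(256, "viridis"), ...)
  graphics::title(sprintf("%s %d (%s)", quantity, component,
                          if (quantity == "tau") "ps" else "%"))
  invisible(lim)
}
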