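#' FLIM data cube
#'
#' Container for a 3-D TCSPC data cube: per-pixel photon-count histograms
#' over time channels.
#'
#' @param data Numeric array, `nx x ny x p` (layout `"xyt"`, default) or
#'   `p x nx x ny` (layout `"txy"`).
#' @param time A [time_axis()] with `p` channels.
#' @param meta Optional named list of acquisition metadata (dwell time,
#'   frames, laser power, ...); informational only.
#' @param layout Axis order of `data`.
#' @return An object of class `flim_cube`: list with `data` (`nx x ny x p`),
#'   `time`, `meta`.
#' @export
flim_cube <- function(data, time, meta = list(), layout = c("xyt", "txy")) {
  layout <- match.arg(layout)
  time <- .as_time_axis(time)
  if (length(dim(data)) != 3L) stop("cube data must be a 3-D array")
  if (layout == "txy") data <- aperm(data, c(2, 3, 1))
  if (dim(data)[3] != time$p) stop("cube time dimension does not match the time axis")
  if (any(data < 0, na.rm = TRUE)) stop("photon counts must be non-negative")
  structure(list(data = data, time = time, meta = meta), class = "flim_cube")
}

#' @export
print.flim_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<flim_cube> %d x %d pixels, %d time channels\n", d[1], d[2], d[3]))
  print(x$time)
  invisible(x)
}

## pixels as rows, column-major over (x, y); the inverse of .traces_to_maps
.cube_traces <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, d[1] * d[2], d[3])
}

#' Trim uninformative time channels
#'
#' Drops the channels before photon counting starts and after it stops;
#' defaults (bins 40 to 960 of a 1024-channel axis, 1-based inclusive) yield
#' 921 channels. The time axis is shifted to start at 0 ns.
#'
#' @param cube A [flim_cube()] (or a [decay_trace()]).
#' @param first,last First and last retained bin, 1-based inclusive.
#' @return Trimmed object of the input's class.
#' @export
trim_channels <- function(cube, first = 40, last = 960) {
  UseMethod("trim_channels")
}

#' @export
trim_channels.flim_cube <- function(cube, first = 40, last = 960) {
  p <- cube$time$p
  .check_trim(first, last, p)
  keep <- seq.int(first, last)
  flim_cube(cube$data[, , keep, drop = FALSE],
            .shift_axis(cube$time, keep), meta = cube$meta)
}

#' @export
trim_channels.flim_trace <- function(cube, first = 40, last = 960) {
  .check_trim(first, last, cube$time$p)
  keep <- seq.int(first, last)
  decay_trace(cube$counts[keep], .shift_axis(cube$time, keep))
}

.check_trim <- function(first, last, p) {
  if (first < 1 || last > p || first >= last)
    stop(sprintf("trim bins must satisfy 1 <= first < last <= %d", p))
}

.shift_axis <- function(time, keep) {
  t <- time$t[keep]
  structure(list(t = t - t[1], dt = time$dt, p = length(keep)),
            class = "flim_time_axis")
}

#' Subtract the constant dark-count offset
#'
#' Estimates a constant background (detector dark current plus ambient light)
#' as the mean of the channels preceding the rise of the decay and subtracts
#' it. The pre-rise window is every channel before the first one exceeding
#' `rise_frac` of the trace maximum; if it holds fewer than `min_window`
#' channels the offset defaults to 0 (with a warning). Negative results are
#' clipped to 0 to keep the traces physical.
#'
#' @param trace A [decay_trace()], numeric vector, or matrix with traces in
#'   rows.
#' @param rise_frac Rise threshold as a fraction of the trace maximum.
#' @param min_window Minimum number of pre-rise channels.
#' @return Same type as the input. The estimated offsets are attached as
#'   attribute `"offset"`.
#' @export
subtract_offset <- function(trace, rise_frac = 0.1, min_window = 5) {
  M <- if (inherits(trace, "flim_trace")) matrix(trace$counts, 1)
       else if (is.matrix(trace)) trace
       else matrix(as.numeric(trace), 1)
  if (ncol(M) < 1) stop("empty trace")
  mx <- apply(M, 1, max)
  rise <- max.col(sweep(M, 1, rise_frac * mx) > 0, ties.method = "first")
  off <- numeric(nrow(M))
  ok <- rise > min_window
  if (any(ok)) {
    for (i in which(ok)) off[i] <- mean(M[i, seq_len(rise[i] - 1L)])
  }
  if (any(!ok))
    warning(sprintf("%d trace(s) rise within the first %d channels; offset set to 0",
                    sum(!ok), min_window))
  out <- pmax(M - off, 0)
  if (inherits(trace, "flim_trace")) {
    res <- decay_trace(out[1, ], trace$time)
    attr(res, "offset") <- off[1]
  } else if (is.matrix(trace)) {
    res <- out
    attr(res, "offset") <- off
  } else {
    res <- out[1, ]
    attr(res, "offset") <- off[1]
  }
  res
}

#' l2-norm normalization
#'
#' Scales a trace (or every row of a trace matrix) to unit Euclidean norm,
#' the final preprocessing step before the chemometric models.
#'
#' @param x Numeric vector or matrix (traces in rows).
#' @return Same shape as `x` with unit-norm rows.
#' @export
l2_normalize <- function(x) {
  if (is.matrix(x)) {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) stop("cannot l2-normalize an all-zero trace (mask it first)")
    x / nrm
  } else {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) stop("cannot l2-normalize an all-zero trace (mask it first)")
    x / nrm
  }
}

#' Mask uninformative pixels
#'
#' Pixels whose decay trace never reaches `threshold` counts carry too little
#' signal to analyze (typically substrate/background) and are excluded;
#' thresholds of 9 (cell-like data) or 5 (dimmer tissue) are typical. Applied
#' to raw, pre-offset counts.
#'
#' @param cube A [flim_cube()].
#' @param threshold Minimum of the per-pixel maximum count for a pixel to be
#'   kept.
#' @return An object of class `flim_mask`: list with `keep` (`nx x ny`
#'   logical matrix) and `threshold`.
#' @export
mask_pixels <- function(cube, threshold = 9) {
  stopifnot(inherits(cube, "flim_cube"), threshold >= 0)
  keep <- apply(cube$data, c(1, 2), max) >= threshold
  structure(list(keep = keep, threshold = threshold), class = "flim_mask")
}

#' @export
print.flim_mask <- function(x, ...) {
  cat(sprintf("<flim_mask> %d / %d pixels kept (threshold %g)\n",
              sum(x$keep), length(x$keep), x$threshold))
  invisible(x)
}

#' Full preprocessing pipeline for a FLIM cube
#'
#' Fixed stage order: channel trimming, low-count pixel masking, offset
#' subtraction, Laguerre deconvolution, l2 normalization. Returns model-ready
#' traces for the kept pixels only.
#'
#' @param cube A [flim_cube()].
#' @param irf A [flim_irf()] on the trimmed time axis.
#' @param basis Optional precomputed [laguerre_basis()]; built from `irf`
#'   when `NULL`.
#' @param trim `c(first, last)` bins, `NULL` for no trimming, or `"auto"`
#'   (default): trim 40-960 when the cube still has 1024 raw channels,
#'   otherwise leave as is.
#' @param mask_threshold Passed to [mask_pixels()].
#' @param nonneg Enforce non-negative fitted traces in the projection
#'   (see [lpd_project()]).
#' @param offset Subtract the pre-rise constant offset (default `TRUE`; the
#'   estimate is 0 for background-free simulated data).
#' @return List with `traces` (kept pixels x p, unit-norm rows,
#'   deconvolved), `raw` (kept pixels x p, trimmed and offset-subtracted
#'   counts), `mask`, `basis`, `time` and `diagnostics` (from
#'   [lpd_fit_quality()]).
#' @export
preprocess_cube <- function(cube, irf, basis = NULL, trim = "auto",
                            mask_threshold = 9, nonneg = TRUE, offset = TRUE) {
  stopifnot(inherits(cube, "flim_cube"))
  if (identical(trim, "auto"))
    trim <- if (cube$time$p == 1024L) c(40, 960) else NULL
  if (!is.null(trim)) cube <- trim_channels(cube, trim[1], trim[2])
  if (is.null(basis)) {
    stopifnot(inherits(irf, "flim_irf"))
    basis <- laguerre_basis(cube$time, irf)
  }
  if (basis$time$p != cube$time$p)
    stop("basis time axis does not match the (trimmed) cube")
  mask <- mask_pixels(cube, mask_threshold)
  traces <- .cube_traces(cube)[as.vector(mask$keep), , drop = FALSE]
  if (nrow(traces) == 0)
    return(list(traces = matrix(0, 0, cube$time$p),
                raw = matrix(0, 0, cube$time$p),
                mask = mask, basis = basis, time = cube$time,
                diagnostics = NULL))
  raw <- if (offset) subtract_offset(traces) else traces
  proj <- lpd_project(raw, basis, nonneg = nonneg)
  ## clip residual negative ripples of the polynomial expansion: the traces
  ## are photon counts, and the training decays the models saw are >= 0
  dec <- pmax(lpd_deconvolve(proj, basis), 0)
  list(traces = l2_normalize(dec), raw = unclass(raw), mask = mask,
       basis = basis, time = cube$time,
       diagnostics = attr(proj, "diagnostics"))
}
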