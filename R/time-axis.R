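#' TCSPC time axis
#'
#' A uniformly sampled time axis for TCSPC decay traces. The default geometry
#' mirrors a common acquisition setting: 1024 raw channels spanning 12.5 ns
#' (channel width 12.5/1024 ns), trimmed to 921 channels starting at 0 ns.
#'
#' @param p Number of time channels.
#' @param dt Channel width in ns.
#' @param t0 Time of the first channel in ns (0 after preprocessing).
#' @return An object of class `flim_time_axis`: list with `t` (vector of
#'   times, ns), `dt` and `p`.
#' @examples
#' tx <- time_axis()
#' tx$p
#' @export
time_axis <- function(p = 921, dt = 12.5 / 1024, t0 = 0) {
  stopifnot(p >= 2, dt > 0)
  structure(list(t = t0 + (seq_len(p) - 1) * dt, dt = dt, p = as.integer(p)),
            class = "flim_time_axis")
}

#' @export
print.flim_time_axis <- function(x, ...) {
  cat(sprintf("<flim_time_axis> %d channels, dt = %.6g ns, span [%.4g, %.4g] ns\n",
              x$p, x$dt, x$t[1], x$t[x$p]))
  invisible(x)
}

.as_time_axis <- function(time) {
  if (inherits(time, "flim_time_axis")) return(time)
  t <- as.numeric(time)
  if (length(t) < 2 || any(diff(t) <= 0))
    stop("time axis must be a strictly increasing vector or a flim_time_axis")
  structure(list(t = t, dt = stats::median(diff(t)), p = length(t)),
            class = "flim_time_axis")
}
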