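#' Read a FLIM cube from a multi-page TIFF
#'
#' Expects one page per time channel (`t` pages of `nx x ny` images), the
#' layout produced by [write_cube_tiff()] and by most TCSPC export tools.
#'
#' @param path TIFF path.
#' @param time A [time_axis()] with as many channels as the file has pages,
#'   or `NULL` to build a default axis (`dt = 12.5/1024` ns).
#' @return A [flim_cube()].
#' @export
read_cube_tiff <- function(path, time = NULL) {
  meta_path <- paste0(path, ".meta.tsv")
  ## float TIFFs written by write_cube_tiff carry a sidecar with the count
  ## scale; integer TIFFs from other tools are read with raw sample values
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !file.exists(meta_path))
  if (!is.list(pages)) pages <- list(pages)
  p <- length(pages)
  if (is.null(time)) time <- time_axis(p = p)
  time <- .as_time_axis(time)
  if (time$p != p) stop(sprintf("TIFF has %d pages but the time axis has %d channels", p, time$p))
  d <- dim(pages[[1]])
  arr <- array(0, c(p, d[1], d[2]))
  for (k in seq_len(p)) arr[k, , ] <- pages[[k]]
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path)
    sc <- meta$value[meta$key == "scale"]
    if (length(sc) == 1 && is.finite(sc)) arr <- arr * sc
  }
  if (min(arr) < -1e-6 * max(abs(arr)))
    stop("TIFF contains substantially negative values; not a photon-count cube")
  arr[arr < 0] <- 0   # float32 round-off
  flim_cube(arr, time, layout = "txy")
}

#' Write a FLIM cube to a multi-page 32-bit float TIFF
#'
#' @param cube A [flim_cube()].
#' @param path Output path.
#' @export
write_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "flim_cube"))
  p <- cube$time$p
  mx <- max(cube$data, 1)
  ## tiff stores [0,1] floats; scale and record the factor in the description
  pages <- lapply(seq_len(p), function(k) cube$data[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  utils::write.table(
    data.frame(key = c("scale", "dt_ns", "p"), value = c(mx, cube$time$dt, p)),
    paste0(path, ".meta.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulated ground truth to CSV
#'
#' One row per pixel (column-major order): `x`, `y`, `tau_i` (ns),
#' `alpha_i` (fractions).
#'
#' @param sim A [make_test_cube()] result.
#' @param path Output CSV path.
#' @export
write_truth_csv <- function(sim, path) {
  stopifnot(inherits(sim, "flim_sim_cube"))
  d <- dim(sim$cube$data)
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  out <- data.frame(grid)
  for (i in seq_len(ncol(sim$tau))) out[[sprintf("tau_%d", i)]] <- sim$tau[, i]
  for (i in seq_len(ncol(sim$alpha))) out[[sprintf("alpha_%d", i)]] <- sim$alpha[, i]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
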