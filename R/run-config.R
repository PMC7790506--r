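#' Read a run configuration from YAML
#'
#' Configuration surface for the `flimlag` command-line script; every field
#' maps onto an argument of the exported functions. Unknown fields are kept
#' verbatim. See `inst/extdata/example-config.yaml` for the full schema.
#'
#' @param path YAML file path.
#' @return Named list of class `flim_run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    n_components = 2L,
    nx = 128L, ny = 128L,
    m_train = 3000L,
    peak_scale = 150,
    noise = TRUE,
    trim = c(40L, 960L),
    mask_threshold = 9,
    orders = 1:15,
    laguerre_alpha = 2,
    x_scale = 1,
    n_pca = 15L, num_trees = 500L, mtry = 12L, sample_fraction = 0.632,
    irf = list(type = "gaussian", center = 0.5, sigma = 0.05))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = c("flim_run_config", "list"))
}

#' Write the resolved configuration next to a run's outputs
#' @param cfg A `flim_run_config`.
#' @param path Output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## Shared helpers for the flimlag script
.config_sim <- function(cfg) {
  sim_config(n_components = cfg$n_components,
             tau_ranges = cfg$tau_ranges, alpha_ranges = cfg$alpha_ranges,
             peak_scale = cfg$peak_scale, noise = cfg$noise)
}

.config_irf <- function(cfg, time) {
  if (!is.null(cfg$irf$file)) return(read_irf(cfg$irf$file, time))
  gaussian_irf(time, center = cfg$irf$center, sigma = cfg$irf$sigma)
}
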