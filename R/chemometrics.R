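#' Train the 2N-model chemometric bundle
#'
#' Fits one PCA (shared across targets) on the normalized training traces and
#' then 2N random-forest regressors on the leading principal-component
#' scores: one forest per lifetime and one per abundance of each component.
#' Hyperparameters default to 15 components, 500 trees, 63.2% of the data per
#' tree drawn without replacement, and 12 candidate features per split.
#'
#' @param train A [make_training_set()] result (or a list with `traces`,
#'   `tau`, `alpha`; lifetimes must be ascending within each row, the
#'   generator's convention).
#' @param n_pca Number of principal components fed to the forests.
#' @param num_trees Trees per forest.
#' @param sample_fraction Per-tree sample fraction (without replacement).
#' @param mtry Candidate features per split.
#' @param seed Integer seed controlling all forest randomness.
#' @return An object of class `flim_bundle`: list with `pca` (`center`,
#'   `rotation`), `forests` (2N [ranger::ranger] models, lifetimes first),
#'   `targets` (data.frame: quantity, component), `n_components`, `p`,
#'   `train_config`, `seed`.
#' @importFrom ranger ranger
#' @export
train_bundle <- function(train, n_pca = 15, num_trees = 500,
                         sample_fraction = 0.632, mtry = 12, seed = 1) {
  X <- train$traces
  stopifnot(is.matrix(X), nrow(X) == nrow(train$tau))
  if (nrow(X) < n_pca)
    stop(sprintf("need at least %d training traces for %d PCA components", n_pca, n_pca))
  N <- ncol(train$tau)
  mtry <- min(mtry, n_pca)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pca)
  scores <- as.data.frame(pca$x[, seq_len(n_pca), drop = FALSE])
  targets <- data.frame(
    quantity = rep(c("tau", "alpha"), each = N),
    component = rep(seq_len(N), 2L))
  ys <- cbind(train$tau, train$alpha)
  forests <- lapply(seq_len(2L * N), function(j)
    ranger::ranger(y = ys[, j], x = scores,
                   num.trees = num_trees, mtry = mtry,
                   sample.fraction = sample_fraction, replace = FALSE,
                   seed = seed + j, num.threads = 1L))
  structure(list(pca = list(center = pca$center,
                            rotation = pca$rotation[, seq_len(n_pca), drop = FALSE]),
                 forests = forests, targets = targets,
                 n_components = N, p = ncol(X),
                 train_config = train$config, seed = seed),
            class = "flim_bundle")
}

#' @export
print.flim_bundle <- function(x, ...) {
  cat(sprintf("<flim_bundle> N = %d components, %d models (PCA %d comps -> RF %d trees), p = %d\n",
              x$n_components, length(x$forests), ncol(x$pca$rotation),
              x$forests[[1]]$num.trees, x$p))
  invisible(x)
}

#' Predict lifetimes and abundances for preprocessed traces
#'
#' Projects the traces with the bundle's fitted PCA (never refitted) and
#' applies each forest. Predicted abundances are clipped at 0 and rescaled to
#' unit sum per trace.
#'
#' @param object A [train_bundle()] result.
#' @param traces `m x p` matrix of deconvolved, l2-normalized traces (same
#'   pipeline as the training data).
#' @param ... Unused.
#' @return List with `tau` and `alpha` (`m x N` matrices; lifetimes in ns,
#'   abundances unit-sum fractions).
#' @export
predict.flim_bundle <- function(object, traces, ...) {
  if (!is.matrix(traces)) traces <- matrix(as.numeric(traces), 1)
  if (ncol(traces) != object$p)
    stop(sprintf("trace length %d does not match the bundle's %d", ncol(traces), object$p))
  scores <- as.data.frame(
    sweep(traces, 2, object$pca$center) %*% object$pca$rotation)
  colnames(scores) <- colnames(object$pca$rotation)
  pred <- vapply(object$forests, function(f)
    stats::predict(f, data = scores, num.threads = 1L)$predictions,
    numeric(nrow(traces)))
  pred <- matrix(pred, nrow(traces))
  N <- object$n_components
  tau <- pred[, seq_len(N), drop = FALSE]
  alpha <- pmax(pred[, N + seq_len(N), drop = FALSE], 0)
  s <- rowSums(alpha)
  zero <- s <= 0
  if (any(zero)) {
    alpha[zero, ] <- 1 / N
    s[zero] <- 1
  }
  list(tau = tau, alpha = alpha / s)
}

#' Predict parameter maps for a whole FLIM cube
#'
#' Runs the full pipeline ([preprocess_cube()] then [predict.flim_bundle()])
#' and folds the predictions back into spatial maps. Lifetimes are reported
#' in ps and abundances in percent, the conventional display units; masked
#' pixels are `NA`.
#'
#' @param bundle A [train_bundle()] result.
#' @param cube A [flim_cube()].
#' @param irf A [flim_irf()] on the trimmed axis.
#' @param ... Passed to [preprocess_cube()] (`basis`, `trim`,
#'   `mask_threshold`, `nonneg`, `offset`).
#' @return An object of class `flim_maps`: list with `tau_ps` and
#'   `alpha_pct` (`nx x ny x N` arrays), `mask`, `n_components` and
#'   `diagnostics`.
#' @export
predict_cube <- function(bundle, cube, irf, ...) {
  stopifnot(inherits(bundle, "flim_bundle"))
  pp <- preprocess_cube(cube, irf, ...)
  keep <- as.vector(pp$mask$keep)
  d <- dim(pp$mask$keep)
  N <- bundle$n_components
  tau <- array(NA_real_, c(d[1], d[2], N))
  alpha <- array(NA_real_, c(d[1], d[2], N))
  if (any(keep)) {
    pred <- predict(bundle, pp$traces)
    for (i in seq_len(N)) {
      m <- matrix(NA_real_, d[1], d[2]); m[keep] <- pred$tau[, i] * 1000
      tau[, , i] <- m
      m <- matrix(NA_real_, d[1], d[2]); m[keep] <- pred$alpha[, i] * 100
      alpha[, , i] <- m
    }
  }
  structure(list(tau_ps = tau, alpha_pct = alpha, mask = pp$mask,
                 n_components = N, diagnostics = pp$diagnostics),
            class = "flim_maps")
}

#' @export
print.flim_maps <- function(x, ...) {
  cat(sprintf("<flim_maps> %d x %d pixels, N = %d (%d kept)\n",
              nrow(x$mask$keep), ncol(x$mask$keep), x$n_components,
              sum(x$mask$keep)))
  invisible(x)
}

#' Save / load a model bundle
#'
#' Versioned single-file persistence (RDS container). Loading refuses a
#' bundle whose trace length does not match `expect_p`.
#'
#' @param bundle A `flim_bundle`.
#' @param path File path.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "flim_bundle"))
  saveRDS(list(format = "flimlpd_bundle", version = 1L, bundle = bundle), path)
  invisible(path)
}

#' @rdname save_bundle
#' @param expect_p Required trace length (`NULL` to skip the check).
#' @export
load_bundle <- function(path, expect_p = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "flimlpd_bundle"))
    stop("not a flimlpd bundle file")
  b <- obj$bundle
  if (!is.null(expect_p) && b$p != expect_p)
    stop(sprintf("bundle was trained on %d-channel traces, data has %d", b$p, expect_p))
  b
}
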