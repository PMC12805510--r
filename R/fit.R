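#' Fit a CG potential by force matching
#'
#' The main fitting interface: takes a trajectory (biased or unbiased), a CG
#' mapping, and trains the RBF-network potential on the projected recomputed
#' forces by minimizing the empirical force-matching loss.  Returns a classed
#' model object with the usual accessor methods (`print`, `summary`, `coef`,
#' `predict`, `residuals`, `plot`, `simulate`).
#'
#' Biases applied along the CG coordinates leave the conditional mean force
#' invariant, so biased trajectories are used directly — no reweighting of the
#' loss — provided forces were recomputed under the unbiased potential.  A
#' warning is emitted when the bias acts on coordinates orthogonal to the
#' mapping (the minimizer is then thermodynamically inconsistent without
#' reweighting).
#'
#' @param dataset a `cg_trajectory`; if its unbiased forces are absent,
#'   `system` must be supplied so they can be recomputed
#' @param mapping a [cg_mapping] with a single CG coordinate
#' @param system optional [cg_system] for force recomputation
#' @param n_frames optional training-set size; an evenly spaced subsample of
#'   the trajectory is used (decorrelated choice)
#' @param n_centers number of RBF centers, spread uniformly over the sampled
#'   CG range (default 64); width = center spacing
#' @param hidden dense-layer widths (default c(64, 64))
#' @param epochs,batch_size,lr,val_frac,patience training controls, see
#'   [train_fm()]
#' @param seed seed controlling initialization, split and shuffling
#' @return an object of class `cgfm`
#' @export
#' @examples
#' \donttest{
#' sys <- make_builtin_system("double_well_1d", list(a = 2))
#' ds <- simulate_trajectory(sys, n_steps = 5e4, seed = 1, stride = 20)
#' fit <- cg_forcematch(ds, axis_mapping(1, 1), sys, epochs = 30)
#' predict(fit, c(-1, 0, 1))
#' }
cg_forcematch <- function(dataset, mapping, system = NULL, n_frames = NULL,
                          n_centers = 64L, hidden = c(64L, 64L),
                          epochs = 200L, batch_size = 512L, lr = 1e-3,
                          val_frac = 0.1, patience = 25L, seed = 1L) {
  stopifnot(inherits(dataset, "cg_trajectory"))
  assert_that(mapping$ncv == 1L,
              "the CG potential model supports one CG coordinate")
  if (is.null(dataset$unbiased_forces)) {
    assert_that(!is.null(system),
                "dataset lacks unbiased forces; supply `system` to recompute")
    dataset <- recompute_unbiased_forces(dataset, system)
  }
  if (dataset$bias$kind != "none" && !bias_on_cg(dataset$bias, mapping))
    warning(paste("bias acts on coordinates orthogonal to the CG mapping;",
                  "the force-matching minimizer is biased without",
                  "reweighting"), call. = FALSE)
  proj <- project_dataset(dataset, mapping)
  x <- as.numeric(proj$cg_positions)
  g <- as.numeric(proj$projected_forces)
  if (!is.null(n_frames)) {
    assert_that(n_frames >= 1 && n_frames <= length(x),
                "n_frames must be between 1 and the trajectory length")
    keep <- unique(round(seq(1, length(x), length.out = n_frames)))
    x <- x[keep]; g <- g[keep]
  }
  centers <- seq(min(x), max(x), length.out = n_centers)
  width <- centers[2] - centers[1]
  # fixed output scale so the raw network works with O(1) targets (see
  # cg_potential_model); essential when projected forces are far from O(1)
  out_scale <- max(stats::sd(g) * width, .Machine$double.eps)
  model <- cg_potential_model(centers, hidden = hidden, seed = seed,
                              out_scale = out_scale)
  tr <- train_fm(model, x, g, epochs = epochs, batch_size = batch_size,
                 lr = lr, seed = seed, val_frac = val_frac,
                 patience = patience)
  structure(
    list(model = tr$model, training = tr, mapping = mapping,
         data = list(n = length(x), cg_range = range(x),
                     cg_positions = x, projected_forces = g),
         bias_kind = dataset$bias$kind,
         system = dataset$metadata$system, seed = as.integer(seed),
         call = match.call()),
    class = "cgfm")
}

#' @export
print.cgfm <- function(x, ...) {
  cat("Coarse-grained potential fit by force matching\n")
  cat(sprintf("  data: %d frames from system '%s' (bias: %s)\n", x$data$n,
              x$system, x$bias_kind))
  cat(sprintf("  model: %d RBF centers on [%.3g, %.3g], hidden layers %s\n",
              x$model$layer_sizes[1], x$data$cg_range[1], x$data$cg_range[2],
              paste(head(x$model$layer_sizes[-1], -1), collapse = "x")))
  cat(sprintf("  final training loss: %.6g (initial %.6g)\n",
              tail(x$training$loss_history, 1), x$training$loss_history[1]))
  invisible(x)
}

#' @export
summary.cgfm <- function(object, ...) {
  h <- object$training$loss_history
  out <- list(n_frames = object$data$n, cg_range = object$data$cg_range,
              n_params = length(object$model$params),
              epochs_run = length(h) - 1, initial_loss = h[1],
              final_loss = tail(h, 1),
              best_val_loss = suppressWarnings(
                min(object$training$val_history, na.rm = TRUE)),
              bias_kind = object$bias_kind, seed = object$seed)
  class(out) <- "summary.cgfm"
  out
}

#' @export
print.summary.cgfm <- function(x, ...) {
  cat("Force-matching fit summary\n")
  cat(sprintf("  frames: %d on CG range [%.4g, %.4g] (bias: %s)\n",
              x$n_frames, x$cg_range[1], x$cg_range[2], x$bias_kind))
  cat(sprintf("  parameters: %d; epochs run: %d\n", x$n_params, x$epochs_run))
  cat(sprintf("  loss: initial %.6g -> final %.6g (best validation %.6g)\n",
              x$initial_loss, x$final_loss, x$best_val_loss))
  invisible(x)
}

#' @export
coef.cgfm <- function(object, ...) object$model$params

#' Predict energy or mean force from a fitted CG potential
#' @param object a `cgfm` fit
#' @param newdata CG coordinate values (default: the training grid range at
#'   200 points)
#' @param type "force" (default, the predicted mean force \eqn{-dU/dR}) or
#'   "energy"
#' @param ... unused
#' @return numeric vector
#' @export
predict.cgfm <- function(object, newdata = NULL,
                         type = c("force", "energy"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% seq(object$data$cg_range[1],
                              object$data$cg_range[2], length.out = 200)
  if (type == "force") predict_mean_force(object$model, newdata)
  else model_energy(object$model, newdata)
}

#' @export
residuals.cgfm <- function(object, ...) {
  object$data$projected_forces -
    model_force(object$model, object$data$cg_positions)
}

#' Plot the fitted mean force (and optionally the exact oracle)
#' @param x a `cgfm` fit
#' @param oracle optional [compute_oracle()] result to overlay
#' @param n grid resolution
#' @param ... passed to [graphics::plot()]
#' @export
plot.cgfm <- function(x, oracle = NULL, n = 400, ...) {
  grid <- seq(x$data$cg_range[1], x$data$cg_range[2], length.out = n)
  f <- predict(x, grid)
  graphics::plot(grid, f, type = "l", xlab = "CG coordinate",
                 ylab = "mean force", ...)
  if (!is.null(oracle))
    graphics::lines(oracle$grid, oracle$mean_force, lty = 2, col = 2)
  invisible(x)
}

#' Simulate CG Langevin dynamics with a fitted potential
#'
#' @param object a `cgfm` fit
#' @param nsim number of independent chains (default 20)
#' @param seed RNG seed
#' @param ... passed to [run_cg_simulation()] (`n_steps`, `dt`,
#'   `energy_abort_threshold`, ...)
#' @return see [run_cg_simulation()]
#' @export
simulate.cgfm <- function(object, nsim = 20, seed = 1L, ...) {
  run_cg_simulation(object$model, n_traj = nsim, seed = seed, ...)
}
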