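#' Project a trajectory onto the CG coordinates
#'
#' Applies the CG mapping identically to positions and (recomputed, unbiased)
#' forces: \eqn{R_i = \xi(r_i)}, \eqn{G_i = \xi(f(r_i))}.
#'
#' @param dataset a `cg_trajectory` with `unbiased_forces` populated (for
#'   biased runs, call [recompute_unbiased_forces()] first)
#' @param mapping a [cg_mapping]
#' @return list with `cg_positions` and `projected_forces`
#'   (frames x CG-dim matrices)
#' @export
project_dataset <- function(dataset, mapping) {
  stopifnot(inherits(dataset, "cg_trajectory"), inherits(mapping, "cg_mapping"))
  if (is.null(dataset$unbiased_forces))
    stop_esfm(paste0("unbiased forces are missing on this biased trajectory; ",
                     "call recompute_unbiased_forces() before projecting"))
  list(cg_positions = apply_mapping(mapping, dataset$positions),
       projected_forces = apply_mapping(mapping, dataset$unbiased_forces))
}

#' CG potential model: RBF features + dense layers
#'
#' A scalar potential \eqn{U(R;\theta)} over a one-dimensional CG coordinate:
#' Gaussian radial basis features
#' \eqn{\phi_j(x) = \exp(-(x - c_j)^2 / 2\sigma^2)} feed fully connected
#' tanh layers with a linear scalar output.  The predicted force is the exact
#' negative derivative of the output with respect to the input (conservative
#' by construction), propagated analytically.
#'
#' @param centers RBF center locations (CG units)
#' @param width RBF width \eqn{\sigma} (default: center spacing)
#' @param hidden integer vector of dense-layer widths (default c(64, 64))
#' @param params optional flat parameter vector \eqn{\theta}; when NULL,
#'   Xavier-initialized from `seed`
#' @param seed initialization seed (used only when `params` is NULL)
#' @param out_scale fixed (non-trainable) output scale: the model energy is
#'   `out_scale` times the raw network output.  RBF features vary on the
#'   length scale `width`, so the raw network force is naturally O(1/width);
#'   setting `out_scale` near `sd(target forces) * width` puts the targets in
#'   the network's natural output range, which matters when forces are far
#'   from O(1) (default 1)
#' @return an object of class `cg_potential`
#' @export
cg_potential_model <- function(centers, width = NULL, hidden = c(64L, 64L),
                               params = NULL, seed = 1L, out_scale = 1) {
  centers <- sort(as.numeric(centers))
  assert_that(length(centers) >= 2, "at least two RBF centers are required")
  width <- width %||% (centers[2] - centers[1])
  assert_that(width > 0, "RBF width must be positive")
  sizes <- as.integer(c(length(centers), hidden, 1L))
  np <- sum(sizes[-1] * sizes[-length(sizes)] + sizes[-1])
  if (is.null(params)) {
    set.seed(as.integer(seed))
    params <- numeric(np)
    off <- 0L
    for (l in seq_len(length(sizes) - 1L)) {
      nin <- sizes[l]; nout <- sizes[l + 1L]
      sdv <- sqrt(2 / (nin + nout))
      params[off + seq_len(nin * nout)] <- rnorm(nin * nout, 0, sdv)
      off <- off + nin * nout + nout  # biases stay zero
    }
  }
  assert_that(length(params) == np,
              "params has length %d but the architecture needs %d",
              length(params), np)
  assert_that(is.numeric(out_scale) && length(out_scale) == 1 &&
                is.finite(out_scale) && out_scale > 0,
              "out_scale must be a single positive finite number")
  structure(list(rbf_centers = centers, rbf_width = width,
                 layer_sizes = sizes, params = as.numeric(params),
                 out_scale = out_scale, activation = "tanh"),
            class = "cg_potential")
}

#' Model energy on CG coordinates
#' @param model a `cg_potential`
#' @param x CG coordinate values
#' @return numeric vector of energies
#' @export
model_energy <- function(model, x) {
  (model$out_scale %||% 1) *
    cpp_net_eval(model$rbf_centers, model$rbf_width, model$layer_sizes,
                 model$params, as.numeric(x))$energy
}

#' Model force -dU/dR on CG coordinates
#' @inheritParams model_energy
#' @return numeric vector of forces
#' @export
model_force <- function(model, x) {
  (model$out_scale %||% 1) *
    cpp_net_eval(model$rbf_centers, model$rbf_width, model$layer_sizes,
                 model$params, as.numeric(x))$force
}

#' Predict the model mean force on a grid
#'
#' Warns when grid points lie outside the RBF-center span (the model
#' extrapolates freely there; no prior potential is applied).
#'
#' @inheritParams model_energy
#' @param grid CG values
#' @return numeric vector of predicted forces \eqn{-dU/dR}
#' @export
predict_mean_force <- function(model, grid) {
  rng <- range(model$rbf_centers)
  if (any(grid < rng[1] | grid > rng[2]))
    warning(sprintf(paste0("%d grid point(s) outside the trained support ",
                           "[%.3g, %.3g]; predictions there are free ",
                           "extrapolation"),
                    sum(grid < rng[1] | grid > rng[2]), rng[1], rng[2]),
            call. = FALSE)
  model_force(model, grid)
}

#' Empirical force-matching loss
#'
#' \eqn{\hat\chi^2(\theta) = \frac{1}{D M}\sum_i \|G_i + \nabla U(R_i;\theta)\|^2}
#' with \eqn{D} the CG dimensionality (here 1) and \eqn{M} the frame count.
#' Either a model or an explicit force curve (`forces`) can be supplied; the
#' latter evaluates the loss of any candidate mean-force function, e.g. the
#' exact oracle mean force.
#'
#' @param model a `cg_potential`, or NULL when `forces` is given
#' @param cg_positions CG coordinates per frame
#' @param projected_forces projected unbiased forces per frame
#' @param forces optional explicit predicted forces (same length), bypassing
#'   the model
#' @return scalar non-negative loss
#' @export
fm_loss <- function(model, cg_positions, projected_forces, forces = NULL) {
  x <- as.numeric(cg_positions)
  g <- as.numeric(projected_forces)
  assert_that(length(x) >= 1, "empty dataset")
  assert_that(length(x) == length(g), "positions/forces length mismatch")
  pred <- if (is.null(forces)) {
    stopifnot(inherits(model, "cg_potential"))
    model_force(model, x)
  } else {
    assert_that(length(forces) == length(x), "forces length mismatch")
    as.numeric(forces)
  }
  mean((g - pred)^2)
}

#' Train a CG potential by stochastic force matching
#'
#' Minimizes the empirical force-matching loss with Adam.  The best
#' parameters by validation loss are returned; a NaN loss aborts training at
#' the last finite checkpoint.
#'
#' @param model a `cg_potential` (initial parameters)
#' @param cg_positions,projected_forces training frames
#' @param epochs passes over the data (0 = no-op; history has one entry)
#' @param batch_size minibatch size (default 512)
#' @param lr Adam learning rate (default 1e-3)
#' @param seed seed for shuffling and the train/validation split
#' @param val_frac validation fraction (default 0.1; 0 disables)
#' @param patience early-stopping patience in epochs (default 25)
#' @return list of class `fm_training`: `model` (best parameters),
#'   `loss_history` (training loss per epoch, starting with the initial
#'   loss), `val_history`, `config_echo`, `dataset_fingerprint`, `aborted`
#' @export
train_fm <- function(model, cg_positions, projected_forces, epochs = 200L,
                     batch_size = 512L, lr = 1e-3, seed = 1L,
                     val_frac = 0.1, patience = 25L) {
  stopifnot(inherits(model, "cg_potential"))
  x <- as.numeric(cg_positions)
  g <- as.numeric(projected_forces)
  n <- length(x)
  assert_that(n >= 1 && n == length(g), "empty or misaligned training data")
  set.seed(as.integer(seed))
  n_val <- floor(val_frac * n)
  perm <- sample.int(n)
  vi <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  ti <- if (n_val > 0) perm[-seq_len(n_val)] else perm
  # the network is trained against targets in its raw output units; losses
  # are reported in physical units (scaled back by out_scale^2)
  s <- model$out_scale %||% 1
  xt <- x[ti]; gt <- g[ti] / s
  xv <- x[vi]; gv <- g[vi] / s
  nt <- length(xt)
  bs <- min(batch_size, nt)

  theta <- model$params
  loss_of <- function(th, xs, gs)
    s^2 * cpp_net_loss_grad(model$rbf_centers, model$rbf_width,
                            model$layer_sizes, th, xs, gs)$loss
  hist <- loss_of(theta, xt, gt)
  vhist <- if (n_val > 0) loss_of(theta, xv, gv) else NA_real_
  best_theta <- theta
  best_val <- if (n_val > 0) vhist[1] else hist[1]
  m1 <- m2 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  it <- 0L
  aborted <- FALSE
  stall <- 0L
  if (epochs > 0) for (ep in seq_len(epochs)) {
    ord <- sample.int(nt)
    nb <- ceiling(nt / bs)
    ok <- TRUE
    for (bidx in seq_len(nb)) {
      sel <- ord[((bidx - 1) * bs + 1):min(bidx * bs, nt)]
      res <- cpp_net_loss_grad(model$rbf_centers, model$rbf_width,
                               model$layer_sizes, theta, xt[sel], gt[sel])
      if (!is.finite(res$loss)) {
        aborted <- TRUE
        ok <- FALSE
        break
      }
      it <- it + 1L
      m1 <- b1 * m1 + (1 - b1) * res$grad
      m2 <- b2 * m2 + (1 - b2) * res$grad^2
      theta <- theta - lr * (m1 / (1 - b1^it)) /
        (sqrt(m2 / (1 - b2^it)) + epsl)
    }
    if (!ok) break
    ltr <- loss_of(theta, xt, gt)
    hist <- c(hist, ltr)
    cur <- if (n_val > 0) loss_of(theta, xv, gv) else ltr
    if (n_val > 0) vhist <- c(vhist, cur)
    if (is.finite(cur) && cur < best_val * (1 - 1e-5)) {
      best_val <- cur
      best_theta <- theta
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  out_model <- model
  out_model$params <- best_theta
  structure(
    list(model = out_model, loss_history = hist, val_history = vhist,
         config_echo = list(epochs = epochs, batch_size = batch_size,
                            lr = lr, seed = as.integer(seed),
                            val_frac = val_frac, patience = patience,
                            optimizer = "adam"),
         dataset_fingerprint = hash_object(list(x = x, g = g)),
         aborted = aborted),
    class = "fm_training")
}
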