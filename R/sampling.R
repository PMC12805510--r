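#' Sample a trajectory with overdamped Langevin dynamics
#'
#' Integrates the Euler--Maruyama discretization of overdamped Langevin
#' dynamics targeting \eqn{\exp(-\beta(u + W\circ\xi))},
#' \deqn{x_{t+1} = x_t - \nabla(u + W)\,\Delta t + \sqrt{2\Delta t/\beta}\,\eta,}
#' with reflective walls at the domain box.  The friction coefficient is
#' absorbed into the time step.  Frames are recorded every `stride` steps
#' after a burn-in.  Noise is drawn once per coordinate per step regardless of
#' recording settings, so changing `stride` or `burn_in` does not shift the
#' random sequence; a fixed seed gives bit-identical output.
#'
#' @param system a [cg_system]
#' @param bias a [cg_bias] (default none)
#' @param n_steps total integrator steps
#' @param dt time step (default: the system's documented default); the
#'   stability heuristic dt x max curvature < 0.1 is the caller's
#'   responsibility when overriding
#' @param seed integer master seed for the noise stream
#' @param stride record every `stride`-th step (default 10)
#' @param burn_in steps discarded before recording (default 10% of `n_steps`)
#' @param x0 starting configuration (default: the system's documented start)
#' @param margin abort if a step overshoots the domain box by more than this
#'   (default: 10% of the smallest box edge)
#' @return a `cg_trajectory`: list with `positions`, `biased_forces`,
#'   `unbiased_forces` (NULL until [recompute_unbiased_forces()] for biased
#'   runs), `bias_energy`, `cv`, `weights`, final `bias` state and `metadata`
#' @export
simulate_trajectory <- function(system, bias = bias_none(), n_steps,
                                dt = NULL, seed, stride = 10L,
                                burn_in = NULL, x0 = NULL, margin = NULL) {
  stopifnot(inherits(system, "cg_system"), inherits(bias, "cg_bias"))
  dt <- dt %||% system$dt
  assert_that(!is.null(dt) && dt > 0, "a positive time step is required")
  burn_in <- as.integer(burn_in %||% floor(0.1 * n_steps))
  stride <- as.integer(stride)
  assert_that(n_steps >= stride && n_steps > burn_in,
              "n_steps must exceed both stride and burn_in")
  x0 <- x0 %||% system$x0
  assert_that(length(x0) == system$dim, "x0 has the wrong dimension")
  margin <- margin %||% (0.1 * min(system$domain_box[2, ] -
                                     system$domain_box[1, ]))
  set.seed(as.integer(seed))
  res <- cpp_langevin(system$code, as.numeric(system$potential_params),
                      system$affine$offset, system$affine$scale,
                      system$affine$escale, as.numeric(x0), system$beta, dt,
                      as.numeric(n_steps), burn_in, stride, system$domain_box,
                      margin, bias_kind_code(bias), bias_cv_type(bias),
                      bias_cv_matrix(bias, system$dim),
                      bias_par_vector(bias), bias$period, bias$deposits)
  final_bias <- bias
  if (bias$kind == "wt_metadynamics") final_bias$deposits <- res$deposits
  n_frames <- nrow(res$positions)
  ds <- structure(
    list(positions = res$positions,
         biased_forces = res$biased_forces,
         unbiased_forces = if (bias$kind == "none") res$biased_forces
                           else NULL,
         bias_energy = res$bias_energy,
         cv = if (bias$kind == "none") NULL else res$cv,
         weights = if (bias$kind == "none") rep(1, n_frames) else NULL,
         bias = final_bias,
         metadata = list(system = system$name,
                         system_hash = system_hash(system),
                         beta = system$beta, dt = dt,
                         n_steps = n_steps, burn_in = burn_in,
                         stride = stride, seed = as.integer(seed),
                         n_frames = n_frames,
                         bias = bias_to_list(final_bias))),
    class = "cg_trajectory")
  ds
}

validate_trajectory <- function(ds) {
  n <- nrow(ds$positions)
  assert_that(nrow(ds$biased_forces) == n &&
                length(ds$bias_energy) == n,
              "frame counts are inconsistent across trajectory arrays")
  if (!is.null(ds$unbiased_forces))
    assert_that(nrow(ds$unbiased_forces) == n,
                "unbiased force array has a different frame count")
  if (!is.null(ds$weights)) {
    assert_that(length(ds$weights) == n, "weight vector length mismatch")
    assert_that(all(is.finite(ds$weights)) && all(ds$weights > 0),
                "weights must be strictly positive and finite")
  }
  invisible(TRUE)
}

#' Recompute unbiased forces on a (possibly biased) trajectory
#'
#' Fills `unbiased_forces` with \eqn{-\nabla u(r)} evaluated at each frame
#' under the unbiased potential.  Idempotent.  Refuses when the system hash
#' does not match the trajectory metadata, to prevent recomputation against
#' the wrong potential.
#'
#' @param dataset a `cg_trajectory`
#' @param system the [cg_system] the trajectory was generated on
#' @return the dataset with `unbiased_forces` populated
#' @export
recompute_unbiased_forces <- function(dataset, system) {
  stopifnot(inherits(dataset, "cg_trajectory"), inherits(system, "cg_system"))
  if (!identical(system_hash(system), dataset$metadata$system_hash))
    stop_esfm(paste0("system hash mismatch: trajectory was generated on '%s' ",
                     "(%s), not on the supplied system (%s)"),
              dataset$metadata$system, dataset$metadata$system_hash,
              system_hash(system))
  dataset$unbiased_forces <- evaluate_force(system, dataset$positions)
  validate_trajectory(dataset)
  dataset
}

#' Importance weights for reweighting biased samples
#'
#' Sets `weights` to \eqn{\omega(r) = \exp(\beta W(\xi(r)))}.  For
#' well-tempered metadynamics the bias energy is re-evaluated from the FINAL
#' deposited bias at each frame's CV (the standard last-bias approximation;
#' these weights are diagnostics, training on metadynamics data uses the
#' recomputed forces directly).  If the exponent would overflow, weights are
#' shifted in log space by their maximum before exponentiation; the shift is
#' recorded in `metadata$weight_log_shift` (self-normalized estimators are
#' unaffected).
#'
#' @param dataset a `cg_trajectory` with `bias_energy` present
#' @return the dataset with `weights` populated
#' @export
compute_importance_weights <- function(dataset) {
  stopifnot(inherits(dataset, "cg_trajectory"))
  beta <- dataset$metadata$beta
  if (dataset$bias$kind == "none") {
    dataset$weights <- rep(1, nrow(dataset$positions))
    return(dataset)
  }
  w_energy <- dataset$bias_energy
  if (dataset$bias$kind == "wt_metadynamics")
    w_energy <- bias_energy_and_force(dataset$bias, dataset$cv)$energy
  assert_that(!is.null(w_energy), "bias_energy is required to compute weights")
  lw <- beta * w_energy
  shift <- 0
  if (max(lw) > 700) {
    shift <- max(lw)
    lw <- lw - shift
  }
  dataset$weights <- exp(lw)
  dataset$metadata$weight_log_shift <- shift
  validate_trajectory(dataset)
  dataset
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory>  %d frames, dim %d, system '%s', bias '%s'\n",
              nrow(x$positions), ncol(x$positions), x$metadata$system,
              x$bias$kind))
  cat(sprintf("  dt = %g, stride = %d, burn_in = %d, seed = %d\n",
              x$metadata$dt, x$metadata$stride, x$metadata$burn_in,
              x$metadata$seed))
  if (is.null(x$unbiased_forces))
    cat("  unbiased forces: not yet recomputed\n")
  invisible(x)
}
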