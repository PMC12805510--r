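#' Central interval of the exact CG density
#'
#' Returns the CG interval containing the requested probability mass
#' (symmetric in tail mass), computed from the oracle marginal by cumulative
#' trapezoidal integration.  Used as the default evaluation interval so that
#' error metrics are not dominated by never-visited regions.
#'
#' @param oracle a [compute_oracle()] result
#' @param mass central probability mass (default 0.999)
#' @return length-2 numeric interval
#' @export
oracle_support_interval <- function(oracle, mass = 0.999) {
  stopifnot(inherits(oracle, "cg_oracle"))
  assert_that(mass > 0 && mass < 1, "mass must be in (0, 1)")
  g <- oracle$grid
  d <- oracle$marginal_density
  seg <- (d[-1] + d[-length(d)]) / 2 * diff(g)
  cum <- c(0, cumsum(seg))
  cum <- cum / cum[length(cum)]
  tail_mass <- (1 - mass) / 2
  lo <- g[max(which(cum <= tail_mass))]
  hi <- g[min(which(cum >= 1 - tail_mass))]
  c(lo, hi)
}

#' RMSE of a model mean force against the exact oracle
#'
#' Evaluates the model force \eqn{-dU/dR} and the oracle mean force on a
#' uniform grid over `interval` (default: the central 99.9% mass of the exact
#' CG density) and returns the root-mean-square difference.  Errors if the
#' interval extends past the oracle grid.
#'
#' @param model a `cg_potential` (or a `cgfm` fit, whose model is used)
#' @param oracle a [compute_oracle()] result
#' @param interval evaluation interval (length 2)
#' @param n grid resolution (default 500)
#' @return list with `rmse`, `grid`, `model_force`, `oracle_force`
#' @export
mean_force_rmse <- function(model, oracle, interval = NULL, n = 500L) {
  if (inherits(model, "cgfm")) model <- model$model
  stopifnot(inherits(model, "cg_potential"), inherits(oracle, "cg_oracle"))
  interval <- interval %||% oracle_support_interval(oracle)
  assert_that(length(interval) == 2 && interval[1] < interval[2],
              "interval must be an increasing length-2 vector")
  grid <- seq(interval[1], interval[2], length.out = n)
  fo <- oracle_mean_force(oracle, grid)
  fm <- suppressWarnings(predict_mean_force(model, grid))
  list(rmse = sqrt(mean((fm - fo)^2)), grid = grid, model_force = fm,
       oracle_force = fo)
}

#' Free energy from a sample histogram
#'
#' Bins samples and returns \eqn{\hat F_b = -\ln \hat p_b} in units of
#' \eqn{k_BT}, shifted so the minimum over occupied bins is zero.  Empty bins
#' get `Inf` and are flagged.  The per-bin standard error follows from
#' binomial counting statistics,
#' \eqn{\mathrm{se}(\hat F_b) = \sqrt{(1-\hat p_b)/(n\hat p_b)}}, which
#' assumes independent frames (an optimistic floor for correlated
#' trajectories).
#'
#' @param samples CG coordinate samples
#' @param bin_edges strictly increasing bin boundaries
#' @return data.frame of class `cg_fe` with `bin_center`, `prob`,
#'   `free_energy`, `se`, `count`, `empty`; attributes `bin_edges`, `n`
#' @export
histogram_free_energy <- function(samples, bin_edges) {
  x <- as.numeric(samples)
  assert_that(length(x) >= 1, "no samples supplied")
  assert_that(all(diff(bin_edges) > 0), "bin edges must be strictly increasing")
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= (length(bin_edges) - 1)
  if (!any(inside))
    stop_esfm("no samples fall inside the binning range [%g, %g]",
              min(bin_edges), max(bin_edges))
  nb <- length(bin_edges) - 1
  cnt <- tabulate(idx[inside], nbins = nb)
  n <- sum(cnt)
  p <- cnt / n
  fe <- -log(p)
  occ <- cnt > 0
  fe[occ] <- fe[occ] - min(fe[occ])
  se <- ifelse(occ, sqrt((1 - p) / (n * pmax(p, .Machine$double.xmin))),
               NA_real_)
  out <- data.frame(bin_center = (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2,
                    prob = p, free_energy = fe, se = se, count = cnt,
                    empty = !occ)
  attr(out, "bin_edges") <- bin_edges
  attr(out, "n") <- n
  class(out) <- c("cg_fe", "data.frame")
  out
}

#' Free-energy divergences between a reference and a sampled histogram
#'
#' Compares a reference bin-probability vector (e.g. the exact oracle density
#' integrated per bin) against model sample counts over the same bins.
#' Returns
#' \itemize{
#'   \item `fe_mse`: mean squared difference of the min-shifted free energies
#'     \eqn{-\ln p} over bins occupied in BOTH histograms;
#'   \item `kl`: \eqn{\sum_b p_{ref,b}\ln(p_{ref,b}/\tilde p_b)} where
#'     \eqn{\tilde p} is the model histogram with an add-half pseudo-count
#'     (applied to the model side only, so empty model bins are penalized
#'     finitely while the reference stays exact).
#' }
#'
#' @param ref_prob reference bin probabilities (non-negative, summing to ~1)
#' @param model_counts integer sample counts on the SAME bins
#' @return list with `fe_mse`, `kl`, `n_joint` (bins entering `fe_mse`)
#' @export
fe_divergences <- function(ref_prob, model_counts) {
  p <- as.numeric(ref_prob)
  cnt <- as.numeric(model_counts)
  assert_that(length(p) == length(cnt),
              "reference and model histograms use different binnings (%d vs %d bins)",
              length(p), length(cnt))
  assert_that(all(p >= 0) && all(cnt >= 0), "negative histogram entries")
  assert_that(sum(cnt) > 0, "model histogram is empty")
  s <- sum(p)
  assert_that(abs(s - 1) < 0.05,
              "reference probabilities sum to %g, not ~1 (wrong binning?)", s)
  p <- p / s
  q_raw <- cnt / sum(cnt)
  joint <- p > 0 & cnt > 0
  assert_that(any(joint), "no jointly occupied bins")
  fe_ref <- -log(p[joint]); fe_ref <- fe_ref - min(fe_ref)
  fe_mod <- -log(q_raw[joint]); fe_mod <- fe_mod - min(fe_mod)
  q_smooth <- (cnt + 0.5) / (sum(cnt) + 0.5 * length(cnt))
  pos <- p > 0
  kl <- sum(p[pos] * log(p[pos] / q_smooth[pos]))
  list(fe_mse = mean((fe_ref - fe_mod)^2), kl = kl, n_joint = sum(joint))
}

#' Langevin simulation driven by a learned CG potential
#'
#' Integrates `n_traj` independent overdamped Langevin chains on the
#' one-dimensional CG coordinate using the model force, Euler--Maruyama with
#' the same convention as [simulate_trajectory()].  Chains are advanced in a
#' batch (one model evaluation per step for all live chains).  A chain is
#' declared unstable and frozen when its model energy exceeds
#' `energy_abort_threshold` or it leaves the trained support (the RBF-center
#' span widened by `support_margin` on each side); its frames from that point
#' are dropped.
#'
#' @param model a `cg_potential`
#' @param n_traj number of chains (default 20)
#' @param n_steps steps per chain (default 10000)
#' @param dt time step (default 1e-3)
#' @param beta inverse temperature of the CG ensemble (default 1)
#' @param x0 starting points; a scalar is recycled, default: equally spaced
#'   over the middle half of the trained support.  Starting points outside
#'   the valid support count as unstable from step 0 (the model cannot
#'   represent that state), so chains may be launched across a common
#'   physical region to compare models with different coverage
#' @param seed RNG seed
#' @param stride record every `stride`-th step (default 10)
#' @param burn_in steps discarded per chain (default 10% of `n_steps`);
#'   applied per chain after stability filtering
#' @param energy_abort_threshold instability cutoff on the model energy;
#'   default: min + 10x the model energy range over the trained support
#' @param support_margin allowed excursion beyond the RBF-center span
#'   (default 25% of the span)
#' @return list of class `cg_simulation`: `samples` (pooled stable frames),
#'   `per_chain` (list of frame vectors, NULL entries for unstable chains),
#'   `n_unstable`, `unstable` (logical per chain), `config`
#' @export
run_cg_simulation <- function(model, n_traj = 20L, n_steps = 10000L,
                              dt = 1e-3, beta = 1, x0 = NULL, seed = 1L,
                              stride = 10L, burn_in = NULL,
                              energy_abort_threshold = NULL,
                              support_margin = NULL) {
  stopifnot(inherits(model, "cg_potential"))
  assert_that(n_traj >= 1 && n_steps >= 1 && dt > 0 && beta > 0,
              "n_traj, n_steps, dt and beta must be positive")
  span <- range(model$rbf_centers)
  width <- span[2] - span[1]
  support_margin <- support_margin %||% (0.25 * width)
  lo <- span[1] - support_margin
  hi <- span[2] + support_margin
  if (is.null(energy_abort_threshold)) {
    eg <- model_energy(model, seq(span[1], span[2], length.out = 512))
    energy_abort_threshold <- min(eg) + 10 * max(diff(range(eg)), 1)
  }
  burn_in <- as.integer(burn_in %||% floor(0.1 * n_steps))
  stride <- as.integer(stride)
  assert_that(n_steps > burn_in, "n_steps must exceed burn_in")
  x0 <- x0 %||% seq(span[1] + 0.25 * width, span[2] - 0.25 * width,
                    length.out = n_traj)
  x <- rep_len(as.numeric(x0), n_traj)

  set.seed(as.integer(seed))
  # a chain asked to start outside the model's valid support is unstable by
  # definition: the model cannot represent its starting state
  alive <- x >= lo & x <= hi
  died_at <- ifelse(alive, NA_integer_, 0L)
  rec_steps <- seq.int(burn_in + 1L, n_steps, by = stride)
  frames <- matrix(NA_real_, nrow = length(rec_steps), ncol = n_traj)
  ri <- 1L
  noise_sd <- sqrt(2 * dt / beta)
  for (s in seq_len(n_steps)) {
    eta <- rnorm(n_traj)  # fixed draw count per step keeps runs reproducible
    if (any(alive)) {
      f <- model_force(model, x[alive])
      x[alive] <- x[alive] + f * dt + noise_sd * eta[alive]
      e <- model_energy(model, pmin(pmax(x[alive], lo), hi))
      bad <- !is.finite(x[alive]) | x[alive] < lo | x[alive] > hi |
        !is.finite(e) | e > energy_abort_threshold
      if (any(bad)) {
        ids <- which(alive)[bad]
        alive[ids] <- FALSE
        died_at[ids] <- s
      }
    }
    if (ri <= length(rec_steps) && s == rec_steps[ri]) {
      frames[ri, alive] <- x[alive]
      frames[ri, !alive] <- NA_real_
      ri <- ri + 1L
    }
  }
  unstable <- !alive
  if (all(unstable))
    warning(sprintf(paste0("all %d chains became unstable (energy threshold ",
                           "%g or support [%g, %g] exceeded); no samples ",
                           "recorded"), n_traj, energy_abort_threshold, lo,
                    hi), call. = FALSE)
  per_chain <- lapply(seq_len(n_traj), function(j) {
    if (unstable[j]) return(NULL)
    frames[, j]
  })
  samples <- unlist(per_chain[!unstable], use.names = FALSE)
  structure(
    list(samples = samples, per_chain = per_chain,
         n_unstable = sum(unstable), unstable = unstable, died_at = died_at,
         config = list(n_traj = n_traj, n_steps = n_steps, dt = dt,
                       beta = beta, seed = as.integer(seed), stride = stride,
                       burn_in = burn_in,
                       energy_abort_threshold = energy_abort_threshold,
                       support = c(lo, hi))),
    class = "cg_simulation")
}

#' @export
print.cg_simulation <- function(x, ...) {
  cat(sprintf("<cg_simulation>  %d chains (%d unstable), %d pooled frames\n",
              x$config$n_traj, x$n_unstable, length(x$samples)))
  invisible(x)
}

#' Full evaluation of a fitted CG potential against the exact oracle
#'
#' Combines the standard checks into one report:
#' \enumerate{
#'   \item mean-force RMSE on the central oracle support
#'     ([mean_force_rmse()]);
#'   \item a CG Langevin simulation with the learned potential
#'     ([run_cg_simulation()]) at the system temperature;
#'   \item free-energy comparison of the simulated histogram against the
#'     exact marginal: per-bin reference probabilities are the oracle density
#'     integrated over each bin (trapezoid on the oracle grid), model
#'     probabilities come from the pooled simulation histogram
#'     ([fe_divergences()]).
#' }
#'
#' @param fit a `cgfm` fit (or a bare `cg_potential` via `model=`)
#' @param oracle a [compute_oracle()] result for the same system and mapping
#' @param beta inverse temperature for the CG simulation (default: 1, the
#'   convention in which the oracle PMF is expressed in \eqn{k_BT};
#'   pass the system beta when the PMF is in energy units)
#' @param n_bins histogram bins over the evaluation interval (default 50)
#' @param interval evaluation interval (default central 99.9% oracle mass)
#' @param ... passed to [run_cg_simulation()]
#' @return list of class `cg_evaluation` with `rmse`, `fe`, `divergences`,
#'   `simulation`, `interval`, `n_bins`
#' @export
evaluate_model <- function(fit, oracle, beta = 1, n_bins = 50L,
                           interval = NULL, ...) {
  model <- if (inherits(fit, "cgfm")) fit$model else fit
  stopifnot(inherits(model, "cg_potential"), inherits(oracle, "cg_oracle"))
  interval <- interval %||% oracle_support_interval(oracle)
  rmse <- mean_force_rmse(model, oracle, interval = interval)
  sim <- run_cg_simulation(model, beta = beta, ...)
  if (length(sim$samples) == 0)
    stop_esfm(paste0("all CG simulation chains became unstable; the model ",
                     "histogram cannot be compared to the oracle"))
  edges <- seq(interval[1], interval[2], length.out = n_bins + 1)
  fe <- histogram_free_energy(sim$samples[sim$samples >= interval[1] &
                                            sim$samples <= interval[2]],
                              edges)
  ref_prob <- vapply(seq_len(n_bins), function(b) {
    gsel <- oracle$grid >= edges[b] & oracle$grid <= edges[b + 1]
    if (sum(gsel) < 2) return(mean(oracle$marginal_density[which.min(
      abs(oracle$grid - (edges[b] + edges[b + 1]) / 2))]) *
        (edges[b + 1] - edges[b]))
    trapz(oracle$grid[gsel], oracle$marginal_density[gsel])
  }, numeric(1))
  div <- fe_divergences(ref_prob / sum(ref_prob), fe$count)
  structure(list(rmse = rmse$rmse, mean_force = rmse, fe = fe,
                 divergences = div, simulation = sim, interval = interval,
                 n_bins = as.integer(n_bins)),
            class = "cg_evaluation")
}

#' @export
print.cg_evaluation <- function(x, ...) {
  cat("CG potential evaluation\n")
  cat(sprintf("  mean-force RMSE on [%.4g, %.4g]: %.6g\n", x$interval[1],
              x$interval[2], x$rmse))
  cat(sprintf("  free energy: MSE %.6g, KL %.6g over %d joint bins\n",
              x$divergences$fe_mse, x$divergences$kl, x$divergences$n_joint))
  cat(sprintf("  simulation: %d/%d chains unstable\n",
              x$simulation$n_unstable, x$simulation$config$n_traj))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param x a `cg_evaluation`
#' @param path output file
#' @return invisibly, the path
#' @export
write_evaluation_report <- function(x, path) {
  stopifnot(inherits(x, "cg_evaluation"))
  rpt <- list(
    mean_force_rmse = x$rmse,
    evaluation_interval = x$interval,
    fe_mse = x$divergences$fe_mse,
    fe_kl = x$divergences$kl,
    joint_bins = x$divergences$n_joint,
    n_bins = x$n_bins,
    n_unstable_chains = x$simulation$n_unstable,
    n_chains = x$simulation$config$n_traj,
    free_energy = list(bin_center = x$fe$bin_center,
                       free_energy = x$fe$free_energy,
                       se = x$fe$se, count = x$fe$count))
  jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
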