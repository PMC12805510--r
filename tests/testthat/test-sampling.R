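# Overdamped Langevin sampling, force recomputation, importance weights.

test_that("unbiased harmonic sampling reproduces the stationary variance", {
  sys <- make_builtin_system("harmonic_1d")
  # stride 300 at dt 0.01 is 3 correlation times, so frames are effectively
  # decorrelated and the plain SE of the sample variance applies
  ds <- simulate_trajectory(sys, n_steps = 3.4e7, seed = 11, stride = 300)
  x <- as.numeric(ds$positions)
  n <- length(x)
  expect_gt(n, 1e5)
  v <- var(x)
  se <- sqrt(2 / (n - 1)) * v
  expect_lt(abs(v - 1), 3 * se)
})

test_that("an umbrella on a harmonic well gives the Gaussian-product variance", {
  sys <- make_builtin_system("harmonic_1d", list(dt = 0.002))
  kappa <- 3
  b <- bias_umbrella(kappa, 0, axis_mapping(1, 1))
  ds <- simulate_trajectory(sys, b, n_steps = 2.8e7, seed = 12, stride = 500)
  x <- as.numeric(ds$positions)
  v <- var(x)
  ref <- 1 / (1 + kappa)  # 1 / (beta (1 + kappa)) at beta = 1
  se <- sqrt(2 / (length(x) - 1)) * v
  expect_lt(abs(v - ref), 3 * se)
})

test_that("unbiased Muller-Brown runs concentrate in the deep basin", {
  ds <- simulate_trajectory(mb_system(), n_steps = 2e6, seed = 13, stride = 50)
  x <- ds$positions[, 1]
  # the saddle toward the other basins projects near -1; a moderate unbiased
  # run should essentially never cross it
  expect_gt(mean(x < -1), 0.99)
})

test_that("sampling is bit-deterministic and recording settings do not shift the stream", {
  sys <- dw_system()
  a <- simulate_trajectory(sys, n_steps = 1e5, seed = 21, stride = 10)
  b <- simulate_trajectory(sys, n_steps = 1e5, seed = 21, stride = 10)
  expect_identical(a$positions, b$positions)
  expect_identical(a$biased_forces, b$biased_forces)
  # doubling the stride yields exactly every other frame of the finer run
  c2 <- simulate_trajectory(sys, n_steps = 1e5, seed = 21, stride = 20)
  idx <- seq(1, nrow(a$positions), by = 2)
  expect_identical(c2$positions, a$positions[idx, , drop = FALSE])
  # a different seed gives a different trajectory
  d <- simulate_trajectory(sys, n_steps = 1e5, seed = 22, stride = 10)
  expect_false(identical(a$positions, d$positions))
})

test_that("biased forces decompose exactly into unbiased force minus bias gradient", {
  b <- bias_umbrella(10, 0.9, mb_ymap())
  ds <- simulate_trajectory(mb_system(), b, n_steps = 2e5, seed = 14,
                            stride = 50)
  ds <- recompute_unbiased_forces(ds, mb_system())
  resid <- ds$biased_forces -
    (ds$unbiased_forces - bias_ambient_gradient(b, ds$positions))
  expect_lt(max(abs(resid)), 1e-10)
  # and the recorded bias energy matches the bias evaluated at the frames
  w <- bias_energy_and_force(b, bias_cv_values(b, ds$positions))$energy
  expect_lt(max(abs(w - ds$bias_energy)), 1e-10)
})

test_that("zero-bias datasets have identical force arrays and unit weights", {
  ds <- simulate_trajectory(dw_system(), n_steps = 1e5, seed = 15, stride = 20)
  expect_identical(ds$biased_forces, ds$unbiased_forces)
  expect_true(all(ds$weights == 1))
  expect_true(all(ds$bias_energy == 0))
  # recomputation is idempotent
  ds2 <- recompute_unbiased_forces(ds, dw_system())
  expect_equal(ds2$unbiased_forces, ds$unbiased_forces, tolerance = 1e-14)
})

test_that("force recomputation refuses a mismatched system", {
  ds <- simulate_trajectory(dw_system(), n_steps = 1e4, seed = 16, stride = 10)
  other <- make_builtin_system("double_well_1d", list(a = 4))
  expect_error(recompute_unbiased_forces(ds, other), "system hash mismatch")
})

test_that("importance weights are exp(beta W) and recover unbiased averages", {
  sys <- make_builtin_system("harmonic_1d", list(dt = 0.002))
  b <- bias_umbrella(1, 1, axis_mapping(1, 1))  # biased mean is 1/2
  ds <- simulate_trajectory(sys, b, n_steps = 1e7, seed = 17, stride = 500)
  ds <- compute_importance_weights(ds)
  expect_equal(ds$weights, exp(1 * ds$bias_energy), tolerance = 1e-14)
  x <- as.numeric(ds$positions)
  expect_gt(mean(x), 0.4)  # the umbrella visibly shifts the raw mean
  rw <- reweighted_expectation(x, ds$weights)
  # SNIS standard error of the mean through the effective sample size
  wn <- ds$weights / sum(ds$weights)
  se <- sqrt(sum(wn^2 * (x - rw$estimate)^2))
  expect_lt(abs(rw$estimate - 0), 3 * se)
})

test_that("sampled histograms converge to the quadrature target for each bias kind", {
  xm <- axis_mapping(1, 1)
  # the unbiased control runs on a lowered barrier (a = 2, ~2 kBT) so the
  # well populations equilibrate within the run; the biased cases flatten
  # the full-height barrier themselves, which is their entire point
  cases <- list(none = list(bias = bias_none(),
                            sys = make_builtin_system("double_well_1d",
                                                      list(a = 2))),
                umbrella = list(bias = bias_umbrella(2, 0.5, xm),
                                sys = dw_system()),
                restraint = list(bias = bias_gaussian_restraint(-4, 0.5, 0, xm),
                                 sys = dw_system()))
  edges <- seq(-1.5, 1.5, length.out = 31)
  grid <- seq(-1.5, 1.5, length.out = 1501)
  for (nm in names(cases)) {
    b <- cases[[nm]]$bias
    sys <- cases[[nm]]$sys
    beta <- sys$beta
    u <- evaluate_potential(sys, matrix(grid))
    ds <- simulate_trajectory(sys, b, n_steps = 1.2e7, seed = 18, stride = 20)
    x <- as.numeric(ds$positions)
    x <- x[x >= -1.5 & x <= 1.5]
    cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), 30)
    p_emp <- cnt / sum(cnt)
    w <- if (b$kind == "none") rep(0, length(grid)) else
      bias_energy_and_force(b, grid)$energy
    dens <- exp(-beta * (u + w - min(u + w)))
    p_ref <- vapply(seq_len(30), function(k) {
      sel <- grid >= edges[k] & grid <= edges[k + 1]
      sum(dens[sel])
    }, numeric(1))
    p_ref <- p_ref / sum(p_ref)
    kl <- sum(ifelse(p_ref > 0 & p_emp > 0,
                     p_ref * log(p_ref / pmax(p_emp, 1e-300)), 0))
    expect_lt(kl, 0.01, label = sprintf("histogram KL for bias '%s'", nm))
  }
})

test_that("metadynamics runs deposit tempered hills and record CV values", {
  sys <- dw_system()
  b <- bias_wt_metadynamics(0.5, 0.1, 500L, 6, axis_mapping(1, 1))
  ds <- simulate_trajectory(sys, b, n_steps = 2e5, seed = 19, stride = 50)
  dep <- ds$bias$deposits
  expect_gt(nrow(dep), 100)
  # effective heights never exceed the initial height and decay where the
  # walker accumulates bias
  expect_true(all(dep[, 2] <= 0.5 + 1e-12))
  expect_lt(min(dep[, 2]), 0.5)
  # weights for metadynamics come from the final bias state
  ds <- compute_importance_weights(ds)
  wfin <- bias_energy_and_force(ds$bias, ds$cv)$energy
  expect_equal(ds$weights, exp(sys$beta * wfin), tolerance = 1e-12)
})

test_that("the sampler validates its inputs", {
  expect_error(simulate_trajectory(dw_system(), n_steps = 5, seed = 1,
                                   stride = 10), "n_steps")
  expect_error(simulate_trajectory(dw_system(), n_steps = 1e4, seed = 1,
                                   x0 = c(1, 2)), "wrong dimension")
})
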