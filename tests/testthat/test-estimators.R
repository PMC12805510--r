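# Nonparametric estimators: binned mean force, reweighting, torque, noise.

test_that("a constant force field yields constant bin means with shrinking SE", {
  set.seed(1)
  x <- runif(5e4, -1, 1)
  g <- rep(2.5, length(x))
  bm <- binned_mean_force(x, g, seq(-1, 1, length.out = 11))
  expect_equal(bm$mean, rep(2.5, 10))
  expect_true(all(bm$se == 0))
  expect_equal(sum(bm$count), length(x))
  expect_identical(attr(bm, "mode"), "direct")
})

test_that("binned mean forces on unbiased harmonic data match the oracle per bin", {
  sys <- make_builtin_system("harmonic_1d")
  orc <- compute_oracle(sys, axis_mapping(1, 1))
  ds <- simulate_trajectory(sys, n_steps = 6e6, seed = 31, stride = 300)
  x <- as.numeric(ds$positions)
  g <- as.numeric(ds$unbiased_forces)
  edges <- seq(-2, 2, length.out = 9)
  bm <- binned_mean_force(x, g, edges, min_count = 50)
  tgt <- oracle_binned_mean_force(orc, edges)
  z <- (bm$mean - tgt) / bm$se
  expect_true(all(abs(z[!bm$low_confidence]) < 3))
  # and the bin means track -x at the density-weighted bin average
  expect_lt(max(abs(bm$mean - tgt)), 0.2)
})

test_that("binned standard errors are calibrated across seeds", {
  # over many independent runs, the oracle bin target should fall within
  # 2 SE of the bin estimate for ~95% of (seed, bin) pairs
  sys <- make_builtin_system("gaussian_2d")
  orc <- compute_oracle(sys, axis_mapping(1, 2))
  edges <- seq(-2, 2, length.out = 9)
  tgt <- oracle_binned_mean_force(orc, edges)
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    ds <- simulate_trajectory(sys, n_steps = 5e5, seed = 1000 + s,
                              stride = 200)
    proj <- project_dataset(ds, axis_mapping(1, 2))
    bm <- binned_mean_force(proj$cg_positions, proj$projected_forces, edges,
                            min_count = 50)
    ok <- !bm$low_confidence & is.finite(bm$se)
    z <- (bm$mean[ok] - tgt[ok]) / bm$se[ok]
    hits <- hits + sum(abs(z) < 2)
    total <- total + length(z)
  }
  cover <- hits / total
  expect_gt(total, 200)
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.995)
})

test_that("self-normalized reweighting has the textbook limits", {
  v <- c(1, 2, 3, 4)
  r <- reweighted_expectation(v, rep(2, 4))
  expect_equal(r$estimate, mean(v))
  expect_equal(r$ess, 4)
  expect_false(r$degenerate)
  expect_warning(r1 <- reweighted_expectation(v, c(1e12, 1, 1, 1)),
                 "degenerate")
  expect_equal(r1$estimate, 1, tolerance = 1e-6)
  expect_lt(r1$ess, 1.1)
  expect_error(reweighted_expectation(v, c(1, 2)), "aligned")
  expect_error(reweighted_expectation(v, c(1, -1, 1, 1)), "positive")
})

test_that("reweighted estimators agree with quadrature for mean, second moment and occupancy", {
  sys <- dw_system()
  xm <- axis_mapping(1, 1)
  # an umbrella at the barrier enhances crossings while keeping weights mild
  b <- bias_umbrella(2, 0, xm)
  ds <- simulate_trajectory(sys, b, n_steps = 1.2e7, seed = 32, stride = 400)
  ds <- compute_importance_weights(ds)
  x <- as.numeric(ds$positions)
  w <- ds$weights
  grid <- seq(-2, 2, length.out = 4001)
  dens <- exp(-sys$beta * evaluate_potential(sys, matrix(grid)))
  dens <- dens / sum(dens)
  refs <- c(mean = sum(dens * grid),
            second = sum(dens * grid^2),
            occupancy = sum(dens[grid > 0]))
  obs <- list(mean = x, second = x^2, occupancy = as.numeric(x > 0))
  for (nm in names(obs)) {
    est <- reweighted_expectation(obs[[nm]], w)
    wn <- w / sum(w)
    se <- sqrt(sum(wn^2 * (obs[[nm]] - est$estimate)^2))
    expect_lt(abs(est$estimate - refs[[nm]]), 4 * se,
              label = sprintf("reweighted %s vs quadrature", nm))
  }
})

test_that("the generalized torque equals the conjugate dihedral force frame-wise", {
  sys <- make_builtin_system("dihedral_chain_4bead")
  pp <- sys$potential_params
  kd <- pp[["kd"]]
  # chains built with every bond at r0 and every bending angle at theta0:
  # bond and angle forces vanish exactly, so the projected force is the
  # dihedral term alone, Q = -dv/dtheta = kd sin(theta), frame for frame
  pos <- t(vapply(seq(-3, 3, length.out = 25), function(th)
    ideal_chain_positions(pp[["r0"]], pp[["theta0"]], th), numeric(12)))
  f <- evaluate_force(sys, pos)
  tq <- generalized_torque(pos, f)
  expect_true(all(tq$valid))
  expect_equal(tq$torque, kd * sin(tq$angle), tolerance = 1e-8)
  # on those frames a chain without the dihedral term exerts no force at all
  sys0 <- make_builtin_system("dihedral_chain_4bead", list(kd = 0))
  tq0 <- generalized_torque(pos, evaluate_force(sys0, pos))
  expect_lt(max(abs(tq0$torque)), 1e-8)
  # off equilibrium the torque is linear in the force, and the dihedral
  # contribution is still exactly kd sin(theta): subtracting the kd = 0
  # chain's torque isolates it on arbitrary perturbed frames
  set.seed(5)
  pert <- matrix(rep(sys$x0, each = 40), nrow = 40) +
    matrix(rnorm(40 * 12, 0, 0.08), nrow = 40)
  tqp <- generalized_torque(pert, evaluate_force(sys, pert))
  tqp0 <- generalized_torque(pert, evaluate_force(sys0, pert))
  expect_equal(tqp$torque - tqp0$torque, kd * sin(tqp$angle),
               tolerance = 1e-10)
})

test_that("the analytic dihedral gradient matches finite differences", {
  sys <- make_builtin_system("dihedral_chain_4bead")
  set.seed(6)
  pos <- sys$x0 + rnorm(12, 0, 0.05)
  grad <- dihedral_gradient(pos)
  h <- 1e-6
  fd <- vapply(seq_len(12), function(j) {
    pp <- pos; pp[j] <- pp[j] + h
    pm <- pos; pm[j] <- pm[j] - h
    zero <- matrix(0, 1, 12)
    ap <- generalized_torque(matrix(pp, 1), zero)$angle
    am <- generalized_torque(matrix(pm, 1), zero)$angle
    (ap - am) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(grad - fd)) / max(abs(fd)), 1e-5)
})

test_that("collinear bond triples flag the dihedral as invalid", {
  pos <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 1, 0), 1, 12)  # beads 1-3 collinear
  f <- matrix(1, 1, 12)
  tq <- generalized_torque(pos, f)
  expect_false(tq$valid[1])
  expect_true(is.na(tq$torque[1]))
})

test_that("the noise estimate isolates the irreducible conditional force variance", {
  # separable 2D Gaussian mapped to x: force_x = -x is deterministic given
  # x, so the conditional variance is zero up to within-bin spread of x
  sys <- make_builtin_system("gaussian_2d")
  ds <- simulate_trajectory(sys, n_steps = 1e6, seed = 33, stride = 100)
  proj <- project_dataset(ds, axis_mapping(1, 2))
  edges <- seq(-3, 3, length.out = 101)
  nz <- estimate_noise(proj$cg_positions, proj$projected_forces, edges)
  expect_lt(nz$pooled, 1e-3)
  # pooled noise equals the FM loss of the binwise-mean predictor over the
  # bins that enter the pooled estimate (count >= 2)
  x <- as.numeric(proj$cg_positions)
  g <- as.numeric(proj$projected_forces)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  inb <- idx >= 1 & idx <= 100
  cnt <- tabulate(idx[inb], 100)
  used <- inb & cnt[pmax(idx, 1)] >= 2
  means <- tapply(g[used], idx[used], mean)
  pred <- as.numeric(means[as.character(idx[used])])
  expect_equal(nz$pooled, fm_loss(NULL, x[used], g[used], forces = pred),
               tolerance = 1e-10)
  # frames in bins below min_count are excluded and reported
  nz2 <- estimate_noise(c(0.4, 0.6, 1.5), c(1, 3, 7), c(0, 1, 2),
                        min_count = 2)
  expect_equal(nz2$n_excluded, 1L)
  expect_equal(nz2$n_used, 2L)
  expect_equal(nz2$pooled, var(c(1, 3)) * 1 / 2)
})

test_that("binned estimation validates its inputs and exports tables", {
  expect_error(binned_mean_force(c(5, 6), c(1, 1), c(0, 1)),
               "no frames fall inside")
  expect_error(binned_mean_force(1, 1, c(1, 0)), "strictly increasing")
  expect_error(binned_mean_force(c(0.5), c(1), c(0, 1), weights = -1),
               "positive")
  bm <- binned_mean_force(runif(100), rnorm(100), seq(0, 1, 0.25))
  path <- tempfile(fileext = ".tsv")
  write_binned_mean_force(bm, path)
  lines <- readLines(path)
  expect_identical(lines[1], "bin_center\tmean\tse\tcount\tmode")
  expect_length(lines, 5)
})
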