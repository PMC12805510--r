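# Shared, lazily computed fixtures.  Heavy objects (oracles, trajectories,
# fits) are built once per test run and memoized here so that independent
# test files can share them without recomputation.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

mb_system <- function() fixture("mb_system", function()
  make_builtin_system("muller_brown"))

mb_xmap <- function() axis_mapping(1, 2)
mb_ymap <- function() axis_mapping(2, 2)

mb_oracle <- function() fixture("mb_oracle", function()
  compute_oracle(mb_system(), mb_xmap()))

mb_interval <- function() fixture("mb_interval", function()
  oracle_support_interval(mb_oracle()))

dw_system <- function() fixture("dw_system", function()
  make_builtin_system("double_well_1d"))

dw_oracle <- function() fixture("dw_oracle", function()
  compute_oracle(dw_system(), axis_mapping(1, 1)))

# A moderately large unbiased double-well trajectory reused by the fitting
# and evaluation tests.
dw_dataset <- function() fixture("dw_dataset", function()
  simulate_trajectory(dw_system(), n_steps = 1e6, seed = 7, stride = 20))

# A force-matched fit on the double well reused by method/evaluation tests.
dw_fit <- function() fixture("dw_fit", function()
  cg_forcematch(dw_dataset(), axis_mapping(1, 1), dw_system(),
                epochs = 60L, seed = 3L))

# The canonical x-axis Gaussian restraint on the rotated Muller-Brown
# surface: a negative Gaussian carved over the deep basin flattens the
# marginal so both basins are visited.
mb_xbias <- function() bias_gaussian_restraint(-110, 0.6, -0.6, mb_xmap())

# Training datasets for the data-efficiency and stability comparisons:
# matched-budget biased/unbiased Muller-Brown runs, five seeds each.
mb_train_dataset <- function(seed, biased) {
  key <- sprintf("mb_train_%s_%d", if (biased) "b" else "u", seed)
  fixture(key, function() {
    if (biased) {
      ds <- simulate_trajectory(mb_system(), mb_xbias(), n_steps = 2e7,
                                seed = seed, stride = 100)
      recompute_unbiased_forces(ds, mb_system())
    } else {
      simulate_trajectory(mb_system(), n_steps = 2e7, seed = seed,
                          stride = 100)
    }
  })
}

# Fits at a given training-set size for the comparisons above.
mb_train_fit <- function(seed, biased, n_frames) {
  key <- sprintf("mb_fit_%s_%d_%d", if (biased) "b" else "u", seed, n_frames)
  fixture(key, function() {
    ds <- mb_train_dataset(if (biased) 100L + seed else 200L + seed, biased)
    cg_forcematch(ds, mb_xmap(), mb_system(), n_frames = n_frames,
                  epochs = 60L, patience = 15L, seed = seed)
  })
}

# Four-bead chain with every bond exactly at r0, both bending angles exactly
# at theta0 and a prescribed dihedral: on such frames the bond and angle
# forces vanish identically.
ideal_chain_positions <- function(r0, theta0, dihedral) {
  b1 <- c(0, 0, 0)
  b2 <- c(r0, 0, 0)
  b3 <- b2 + r0 * c(-cos(theta0), sin(theta0), 0)
  bc <- (b3 - b2) / r0
  ab <- b2 - b1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  b4 <- b3 + r0 * (-cos(theta0) * bc +
                     sin(theta0) * (cos(dihedral) * m + sin(dihedral) * n))
  c(b1, b2, b3, b4)
}

# Analytic dihedral gradient of the four-point dihedral, recovered through
# the exported torque interface: with unit force on coordinate j the torque
# equals grad_j / |grad|^2, and sum_j torque_j^2 = 1 / |grad|^2.
dihedral_gradient <- function(positions) {
  pos <- matrix(positions, nrow = 1)
  tq <- vapply(seq_len(12), function(j) {
    f <- matrix(0, 1, 12); f[1, j] <- 1
    generalized_torque(pos, f)$torque
  }, numeric(1))
  tq / sum(tq^2)
}
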