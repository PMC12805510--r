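# Analytic model systems: potentials, gradients, registry.

test_that("the builtin registry lists the model systems and rejects unknown names", {
  expect_setequal(builtin_systems(),
                  c("harmonic_1d", "double_well_1d", "gaussian_2d",
                    "muller_brown", "dihedral_chain_4bead"))
  expect_error(make_builtin_system("unknown"), "unknown builtin system")
  expect_error(make_builtin_system("harmonic_1d", list(zeta = 1)),
               "unknown override")
})

test_that("simple closed-form potential values are exact", {
  h <- make_builtin_system("harmonic_1d")
  expect_equal(evaluate_potential(h, 0), 0)
  expect_equal(as.numeric(evaluate_force(h, 2)), -2)

  dw <- dw_system()  # u(x) = a (x^2 - 1)^2, a = 8
  expect_equal(evaluate_potential(dw, c(-1)), 0)
  expect_equal(evaluate_potential(dw, c(1)), 0)
  expect_equal(evaluate_potential(dw, 0), 8)
  # symmetric about 0
  xs <- seq(0.1, 1.9, by = 0.3)
  expect_equal(evaluate_potential(dw, matrix(xs)),
               evaluate_potential(dw, matrix(-xs)))

  g2 <- make_builtin_system("gaussian_2d")  # u = (kx x^2 + ky y^2)/2
  expect_equal(evaluate_potential(g2, c(1, 2)), 0.5 + 2)
})

test_that("analytic forces match central finite differences on every builtin", {
  h <- 1e-5
  for (name in builtin_systems()) {
    sys <- make_builtin_system(name)
    set.seed(42)
    lo <- sys$domain_box[1, ]; hi <- sys$domain_box[2, ]
    # interior points, shrunk 10% from the walls
    n <- 500L
    pos <- sapply(seq_len(sys$dim), function(j)
      runif(n, lo[j] + 0.05 * (hi[j] - lo[j]), hi[j] - 0.05 * (hi[j] - lo[j])))
    pos <- matrix(pos, nrow = n)
    if (name == "dihedral_chain_4bead") {
      # random interior points of a 12D box are unphysical (huge energies);
      # perturb the equilibrium geometry instead
      pos <- matrix(rep(sys$x0, each = n), nrow = n) +
        matrix(rnorm(n * 12, 0, 0.1), nrow = n)
    }
    f <- evaluate_force(sys, pos)
    scale <- max(abs(f), 1)
    for (j in seq_len(sys$dim)) {
      pp <- pos; pp[, j] <- pp[, j] + h
      pm <- pos; pm[, j] <- pm[, j] - h
      fd <- -(evaluate_potential(sys, pp) - evaluate_potential(sys, pm)) /
        (2 * h)
      expect_lt(max(abs(fd - f[, j])) / scale, 1e-5,
                label = sprintf("FD force mismatch for %s, coordinate %d",
                                name, j))
    }
  }
})

test_that("the Muller-Brown surface has its documented basin structure", {
  sys <- mb_system()
  # stationary points in the rotated frame, located by refining from the
  # known canonical minima: deep minimum, middle minimum, shallow minimum
  mins <- rbind(c(-1.4641769147, 0.4963597400),
                c(0.3783711414, 0.4963596511),
                c(-0.3901438613, 0.2609448935))
  e <- evaluate_potential(sys, mins)
  # every listed point is a stationary point with tiny force norm
  fn <- sqrt(rowSums(evaluate_force(sys, mins)^2))
  expect_lt(max(fn), 1e-4)
  # a dense scan on the segment between the two lowest minima crosses a
  # barrier strictly above both basin energies
  tseq <- seq(0, 1, length.out = 400)
  seg <- cbind(mins[1, 1] + tseq * (mins[3, 1] - mins[1, 1]),
               mins[1, 2] + tseq * (mins[3, 2] - mins[1, 2]))
  barrier <- max(evaluate_potential(sys, seg))
  expect_gt(barrier, max(e[1], e[3]))
  # global-minimum basin lies strictly below the saddle region
  expect_lt(e[1], barrier)
  # the documented beta puts that barrier several kBT above the basins,
  # so unbiased dynamics rarely crosses
  expect_gt(sys$beta * (barrier - e[1]), 5)
})

test_that("the four-bead chain's dihedral energy is minimal at the trans angle", {
  sys <- make_builtin_system("dihedral_chain_4bead")
  # scan the dihedral by rotating bead 4 about the bead2-bead3 axis
  # (Rodrigues formula); bonds and bending angles are unchanged, so the
  # energy scan isolates u_dihedral = kd (1 + cos phi), minimal at phi = pi
  base <- sys$x0
  b2 <- base[4:6]; b3 <- base[7:9]; b4 <- base[10:12]
  axis <- (b3 - b2) / sqrt(sum((b3 - b2)^2))
  rel <- b4 - b3
  rotate <- function(v, k, ang)
    v * cos(ang) + c(k[2] * v[3] - k[3] * v[2],
                     k[3] * v[1] - k[1] * v[3],
                     k[1] * v[2] - k[2] * v[1]) * sin(ang) +
      k * sum(k * v) * (1 - cos(ang))
  angs <- seq(-pi, pi, length.out = 181)
  pos <- t(vapply(angs, function(a) {
    p <- base
    p[10:12] <- b3 + rotate(rel, axis, a)
    p
  }, numeric(12)))
  e <- evaluate_potential(sys, pos)
  phi <- generalized_torque(pos, matrix(0, nrow(pos), 12))$angle
  kd <- sys$potential_params[["kd"]]
  # bond and angle energies are constant along the scan, so subtracting the
  # kd = 0 chain's energy isolates exactly kd (1 + cos phi)
  sys0 <- make_builtin_system("dihedral_chain_4bead", list(kd = 0))
  e0 <- evaluate_potential(sys0, pos)
  expect_equal(e - e0, kd * (1 + cos(phi)), tolerance = 1e-10)
  expect_equal(abs(phi[which.min(e)]), pi, tolerance = 0.05)
})

test_that("affine transforms re-express the surface without changing physics", {
  base <- make_builtin_system("harmonic_1d")
  shifted <- make_builtin_system("harmonic_1d",
                                 list(affine = list(offset = 2, scale = 0.5,
                                                    escale = 3),
                                      domain_box = rbind(-2, 6)))
  # u'(x) = escale * u((x - offset)/scale)
  xs <- seq(-1, 5, by = 0.5)
  expect_equal(evaluate_potential(shifted, matrix(xs)),
               3 * evaluate_potential(base, matrix((xs - 2) / 0.5)))
  # and the hash distinguishes the two parameterizations
  expect_false(identical(system_hash(base), system_hash(shifted)))
})

test_that("system validation rejects malformed specifications", {
  expect_error(make_builtin_system("harmonic_1d", list(beta = -1)),
               "beta")
  expect_error(evaluate_potential(mb_system(), c(1, 2, 3)),
               "not a multiple of system dimension")
  expect_error(make_builtin_system("harmonic_1d", list(k = NA_real_)),
               "finite")
})

test_that("parameter overrides propagate into energies and the system hash", {
  dw2 <- make_builtin_system("double_well_1d", list(a = 2))
  expect_equal(evaluate_potential(dw2, 0), 2)
  expect_false(identical(system_hash(dw2), system_hash(dw_system())))
})
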