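# CG potential model, force-matching loss and training loop.

test_that("dataset projection applies one mapping to positions and forces", {
  ds <- dw_dataset()
  proj <- project_dataset(ds, axis_mapping(1, 1))
  expect_identical(as.numeric(proj$cg_positions), as.numeric(ds$positions))
  expect_identical(as.numeric(proj$projected_forces),
                   as.numeric(ds$unbiased_forces))
  # x-projection of 2D data picks the x components
  ds2 <- simulate_trajectory(mb_system(), n_steps = 1e4, seed = 41,
                             stride = 50)
  p2 <- project_dataset(ds2, mb_xmap())
  expect_identical(as.numeric(p2$cg_positions), ds2$positions[, 1])
  expect_identical(as.numeric(p2$projected_forces), ds2$unbiased_forces[, 1])
  # biased data without recomputed forces is refused
  dsb <- simulate_trajectory(mb_system(), bias_umbrella(1, 0, mb_ymap()),
                             n_steps = 1e4, seed = 42, stride = 50)
  expect_error(project_dataset(dsb, mb_xmap()),
               "recompute_unbiased_forces")
  # non-orthonormal mappings are rejected at construction
  expect_error(cg_mapping(matrix(c(1, 1), 1, 2)), "orthonormal")
})

test_that("the model force is the exact negative gradient of its energy", {
  model <- cg_potential_model(seq(-2, 2, length.out = 32), seed = 8,
                              out_scale = 3.7)
  xs <- seq(-1.9, 1.9, length.out = 41)
  h <- 1e-5
  fd <- -(model_energy(model, xs + h) - model_energy(model, xs - h)) / (2 * h)
  f <- model_force(model, xs)
  expect_lt(max(abs(f - fd)) / max(abs(f)), 1e-5)
  # line integral of the force equals the energy drop (gradient theorem)
  dense <- seq(-1.5, 1.5, length.out = 20001)
  fint <- sum(diff(dense) * (model_force(model, dense)[-1] +
                               model_force(model, dense)[-20001]) / 2)
  expect_equal(fint, model_energy(model, -1.5) - model_energy(model, 1.5),
               tolerance = 1e-6)
})

test_that("model construction validates its inputs and is deterministic", {
  expect_error(cg_potential_model(1), "at least two")
  expect_error(cg_potential_model(c(0, 1), out_scale = -1), "out_scale")
  expect_error(cg_potential_model(c(0, 1), params = c(1, 2)),
               "architecture needs")
  m1 <- cg_potential_model(c(0, 1), seed = 3)
  m2 <- cg_potential_model(c(0, 1), seed = 3)
  expect_identical(m1$params, m2$params)
  expect_identical(model_energy(m1, 0.5), model_energy(m2, 0.5))
})

test_that("the force-matching loss has its closed-form limits", {
  set.seed(9)
  x <- runif(200, -1, 1)
  model <- cg_potential_model(seq(-1, 1, length.out = 16), seed = 2)
  g <- model_force(model, x)
  expect_equal(fm_loss(model, x, g), 0)                  # perfect match
  expect_equal(fm_loss(NULL, x, g, forces = rep(0, 200)),
               mean(g^2))                                # zero-force model
  expect_error(fm_loss(model, numeric(0), numeric(0)), "empty dataset")
  expect_error(fm_loss(model, x, g[-1]), "length mismatch")
})

test_that("training on abundant harmonic data recovers the linear mean force", {
  sys <- make_builtin_system("harmonic_1d")
  ds <- simulate_trajectory(sys, n_steps = 2e6, seed = 43, stride = 100)
  fit <- cg_forcematch(ds, axis_mapping(1, 1), sys, epochs = 60L, seed = 1L)
  grid <- seq(-1.5, 1.5, length.out = 101)
  pred <- predict(fit, grid)
  slope <- coef(lm(pred ~ grid))[2]
  expect_lt(abs(slope - (-1)) / 1, 0.02)
})

test_that("training recovers a known teacher model from noiseless forces", {
  centers <- seq(-1, 1, length.out = 32)
  teacher <- cg_potential_model(centers, seed = 77, out_scale = 0.2)
  set.seed(10)
  x <- runif(8000, -1, 1)
  g <- model_force(teacher, x)
  student <- cg_potential_model(centers, seed = 5,
                                out_scale = max(sd(g) * (centers[2] - centers[1]),
                                                .Machine$double.eps))
  tr <- train_fm(student, x, g, epochs = 400L, lr = 2e-3, seed = 5,
                 patience = 100L)
  grid <- seq(-0.95, 0.95, length.out = 200)
  rmse <- sqrt(mean((model_force(tr$model, grid) -
                       model_force(teacher, grid))^2))
  expect_lt(rmse, 1e-3 * max(1, max(abs(model_force(teacher, grid)))))
})

test_that("training bookkeeping matches its contract", {
  set.seed(11)
  x <- runif(500, -1, 1); g <- -x + rnorm(500, 0, 0.1)
  model <- cg_potential_model(seq(-1, 1, length.out = 8), hidden = 8L,
                              seed = 1)
  # zero epochs: parameters untouched, single-entry history
  tr0 <- train_fm(model, x, g, epochs = 0L)
  expect_identical(tr0$model$params, model$params)
  expect_length(tr0$loss_history, 1)
  # real training: finite history, final <= initial, reproducible
  tra <- train_fm(model, x, g, epochs = 15L, seed = 2)
  trb <- train_fm(model, x, g, epochs = 15L, seed = 2)
  expect_true(all(is.finite(tra$loss_history)))
  expect_lte(tail(tra$loss_history, 1), tra$loss_history[1])
  expect_identical(tra$loss_history, trb$loss_history)
  expect_identical(tra$model$params, trb$model$params)
  expect_identical(tra$dataset_fingerprint, trb$dataset_fingerprint)
  # a non-finite loss aborts at the last finite checkpoint
  bad <- model
  bad$params[] <- 1e200
  trc <- train_fm(bad, x, g, epochs = 5L)
  expect_true(trc$aborted)
})

test_that("out-of-support prediction warns instead of applying a prior", {
  model <- cg_potential_model(seq(-1, 1, length.out = 8), seed = 1)
  expect_warning(predict_mean_force(model, c(-2, 0, 2)),
                 "outside the trained support")
  expect_silent(predict_mean_force(model, c(-0.5, 0.5)))
})
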