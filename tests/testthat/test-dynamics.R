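test_that("example specifications encode the expected sparse structure", {
  expect_equal(make_example("poly1d")$truth$k, 3)
  expect_equal(make_example("lorenz")$truth$k, 7)
  expect_equal(make_example("seir")$truth$k, 6)   # S, E, I equations only
  expect_equal(make_example("burgers")$truth$k, 2)
  expect_equal(make_example("cubic2d")$truth$k, 4)
  expect_error(make_example("vanderpol"))
  # the Lorenz first equation carries 10 (y - x)
  lor <- make_example("lorenz")
  labels <- rownames(lor$truth$coefficients)
  expect_equal(unname(lor$truth$coefficients[labels == "y", 1]), 10)
  expect_equal(unname(lor$truth$coefficients[labels == "x", 1]), -10)
})

test_that("the closed SEIR map conserves total population exactly", {
  spec <- make_example("seir")
  total <- sum(spec$train_ics[1, ])
  sim <- simulate_system(spec, spec$train_ics[1, ], 250, 1, noise_sd = 0)
  expect_lt(max(abs(rowSums(sim$clean) - total)) / total, 1e-12)
})

test_that("seeded noise is reproducible and absent at noise_sd = 0", {
  spec <- make_example("poly1d")
  a <- simulate_system(spec, 2, 2, 0.01, seed = 5, noise_sd = 1e-3)
  b <- simulate_system(spec, 2, 2, 0.01, seed = 5, noise_sd = 1e-3)
  expect_identical(a$states, b$states)
  expect_false(identical(a$states, a$clean))
  c0 <- simulate_system(spec, 2, 2, 0.01, noise_sd = 0)
  expect_identical(c0$states, c0$clean)
})

test_that("exact derivatives satisfy the library identity on noiseless samples", {
  for (name in c("poly1d", "lorenz")) {
    spec <- make_example(name)
    sim <- simulate_system(spec, spec$train_ics[1, ], 1, 0.01, noise_sd = 0)
    theta <- evaluate_library(spec$library, sim$clean)
    expect_lt(max(abs(sim$derivs - theta %*% spec$xi_true)), 1e-10)
  }
})

test_that("ODE sampling is converged with respect to integrator tolerance", {
  spec <- make_example("poly1d")
  E <- sindyic:::exponent_matrix(spec$library)
  times <- seq(0, 4, by = 0.05)
  tight <- sindyic:::integrate_poly_ode(E, spec$xi_true, 2, times,
                                        rtol = 1e-8, atol = 1e-10)
  tighter <- sindyic:::integrate_poly_ode(E, spec$xi_true, 2, times,
                                          rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(tight$states - tighter$states)) / max(abs(tight$states)), 1e-6)
})

test_that("candidate simulation reproduces the truth and flags divergence", {
  spec <- make_example("poly1d")
  truth_traj <- simulate_candidate(spec$truth, spec$library, 2, 4, 0.01, "ode",
                                   rtol = 1e-8, atol = 1e-10)
  ref <- simulate_system(spec, 2, 4, 0.01, noise_sd = 0)
  expect_false(truth_traj$diverged)
  expect_lt(max(abs(truth_traj$states - ref$clean)), 1e-6)

  # all-zero model: constant trajectory at the initial condition
  zero <- sindyic:::new_sindy_model(matrix(0, spec$library$p, 1),
                                    sindyic:::term_labels(spec$library),
                                    "stlsq", 1)
  flat <- simulate_candidate(zero, spec$library, 1.3, 1, 0.1, "ode")
  expect_equal(unname(flat$states[, 1]), rep(1.3, 11), tolerance = 1e-12)

  # finite-time blow-up (xdot = x^2) is data, not an exception
  xi <- matrix(0, spec$library$p, 1); xi[3, 1] <- 1
  bomb <- sindyic:::new_sindy_model(xi, sindyic:::term_labels(spec$library),
                                    "stlsq", 0)
  out <- simulate_candidate(bomb, spec$library, 2, 4, 0.01, "ode")
  expect_true(out$diverged)
  expect_true(is.finite(out$diverge_time) && out$diverge_time <= 4)
  expect_null(out$states)
})

test_that("an overfit cubic model with sign-flipped damping diverges", {
  spec <- make_example("cubic2d")
  xi <- spec$xi_true
  labels <- rownames(spec$truth$coefficients)
  xi[labels == "x^3", 1] <- +0.5   # anti-damping
  xi[labels == "x^5", 1] <- 0.2    # spurious high-order growth
  bad <- sindyic:::new_sindy_model(xi, labels, "stlsq", 0)
  out <- simulate_candidate(bad, spec$library, c(2, 0), 10, 0.01, "ode")
  expect_true(out$diverged)
})

test_that("generated datasets have the documented measurement counts", {
  spec <- make_example("poly1d")
  d <- generate_dataset(spec, n_train = 3, n_valid = 7, duration = 2,
                        step = 0.01, noise_sd = 1e-3, seed = 2)
  expect_equal(length(d$train$trajectories), 3L)
  expect_equal(length(d$valid$trajectories), 7L)
  # validation measurement count: (number of ICs) x (samples per instance)
  n_samples <- vapply(d$valid$trajectories, function(tr) length(tr$times), 0L)
  expect_true(all(n_samples == 2 / 0.01 + 1))
  expect_equal(sum(n_samples), 7 * 201)
  # training and validation share step and duration
  expect_equal(d$train$step, d$valid$step)
  expect_error(generate_dataset(spec, n_train = 0, seed = 1), "n_train")
})

test_that("the Burgers solver approximately conserves total mass", {
  spec <- make_example("burgers")
  sim <- simulate_system(spec, c(1, -2), 5, 0.1, noise_sd = 0)
  dx <- diff(spec$spatial_grid)[1]
  mass <- rowSums(sim$clean) * dx
  expect_lt(diff(range(mass)) / mass[1], 1e-3)
})

test_that("simulating the spec and its candidate-model form agree", {
  spec <- make_example("seir")
  full <- simulate_system(spec, spec$train_ics[1, ], 100, 1, noise_sd = 0)
  sub <- simulate_candidate(spec$truth, spec$library, spec$train_ics[1, 1:3],
                            100, 1, "map")
  expect_lt(max(abs(full$clean[, 1:3] - sub$states)), 1e-12)
})
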