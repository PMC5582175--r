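# Fixtures are generated in code and memoized so expensive simulations run
# once per test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Noiseless 1-D polynomial example with exact derivatives: the cleanest
# regression problem in the package, used by several suites.
poly1d_noiseless <- function() fixture("poly1d_noiseless", {
  spec <- make_example("poly1d")
  d <- generate_dataset(spec, n_valid = 2, noise_sd = 0, seed = 42)
  reg <- build_regression_data(spec$library, d$train, d$derivs, "ode")
  list(spec = spec, data = d, design = reg$design, target = reg$target)
})

# Small random single-equation regression problem (for oracle comparisons).
random_regression <- function(p, m = 60, seed = 99) {
  set.seed(seed)
  design <- matrix(rnorm(m * p), m, p)
  colnames(design) <- paste0("f", seq_len(p))
  beta <- numeric(p)
  beta[seq_len(min(2, p))] <- c(1.5, -0.7)[seq_len(min(2, p))]
  target <- design %*% beta + rnorm(m, sd = 0.05)
  list(design = design, target = target)
}

# Noiseless Burgers training data with exact time derivatives.
burgers_noiseless <- function() fixture("burgers_noiseless", {
  spec <- make_example("burgers")
  d <- generate_dataset(spec, n_valid = 1, noise_sd = 0, seed = 42)
  reg <- build_regression_data(spec$library, d$train, d$derivs, "pde",
                               spatial_grid = spec$spatial_grid)
  list(spec = spec, design = reg$design, target = reg$target)
})
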