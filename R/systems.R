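# ---- trajectory containers ----------------------------------------------

new_trajectory <- function(x0, times, states, diverged = FALSE,
                           diverge_time = NA_real_) {
  structure(list(x0 = x0, times = times, states = states,
                 diverged = diverged, diverge_time = diverge_time),
            class = "sindy_trajectory")
}

#' Construct a trajectory set
#'
#' A trajectory set is a collection of observed or simulated state time
#' series sharing one sampling step and duration, plus the noise level used
#' to generate them and their role (training or validation).
#'
#' @param trajectories list of trajectory records (`x0`, `times`, `states`).
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise (>= 0).
#' @param step sampling step shared by all trajectories.
#' @param role `"training"` or `"validation"`.
#' @return object of class `trajectory_set`.
#' @export
trajectory_set <- function(trajectories, noise_sd = 0, step = NULL,
                           role = c("training", "validation")) {
  role <- match.arg(role)
  if (!length(trajectories)) stop("trajectory set is empty")
  if (is.null(step)) step <- diff(trajectories[[1]]$times)[1]
  structure(list(trajectories = trajectories, noise_sd = noise_sd,
                 step = step, role = role),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  tr <- x$trajectories[[1]]
  cat(sprintf("Trajectory set (%s): %d trajectories, %d samples each, noise sd %g\n",
              x$role, length(x$trajectories), length(tr$times), x$noise_sd))
  invisible(x)
}

# ---- worked-example system specifications -------------------------------

set_xi <- function(lib, xi, exponents, eq, value, derivative_order = 0L) {
  for (i in seq_along(lib$terms)) {
    tm <- lib$terms[[i]]
    if (identical(as.integer(tm$exponents), as.integer(exponents)) &&
        tm$derivative_order == derivative_order) {
      xi[i, eq] <- value
      return(xi)
    }
  }
  stop("term not found in library")
}

#' Ground-truth specifications for the five worked example systems
#'
#' Returns a fully configured system specification: the true dynamics encoded
#' as a sparse coefficient matrix over a declared feature library (so the
#' truth is itself a candidate model), plus documented defaults for training
#' design, sampling, noise level and initial-condition sampling.
#'
#' The examples are:
#' \describe{
#'   \item{`poly1d`}{one-state polynomial ODE `x' = x - 0.2 x^3 - 0.1 x^4`
#'     (3 true terms, degree-5 library).}
#'   \item{`cubic2d`}{damped cubic oscillator `x' = -0.1 x^3 + 2 y^3`,
#'     `y' = -2 x^3 - 0.1 y^3` (4 true terms, degree-6 library with 28
#'     monomials spanning 2^28 - 1 candidate subset models).}
#'   \item{`seir`}{closed discrete SEIR epidemic map over a population of
#'     1000 individuals: `S_{k+1} = S - beta S I`,
#'     `E_{k+1} = E + beta S I - sigma E`, `I_{k+1} = I + sigma E - gamma I`,
#'     `R_{k+1} = R + gamma I` with per-contact transmission `beta = 3e-4`
#'     (0.3 per capita), incubation `sigma = 0.1` and recovery `gamma = 0.04`
#'     per step. The model library covers (S, E, I) only (R is redundant);
#'     the true (S, E, I) system has 6 nonzero terms over the quadratic
#'     library.}
#'   \item{`lorenz`}{Lorenz equations with `sigma = 10`, `rho = 28`,
#'     `beta = 8/3` (7 true terms over the quadratic library).}
#'   \item{`burgers`}{Burgers' equation `u_t = -u u_x + 0.1 u_xx` on
#'     `x in [-8, 8]` with Gaussian initial fields of varying amplitude and
#'     center (2 true terms over the `u^a * d^b u/dx^b` library).}
#' }
#'
#' @param name one of `"poly1d"`, `"cubic2d"`, `"seir"`, `"lorenz"`,
#'   `"burgers"`.
#' @return object of class `system_spec` with elements `kind` (`"ode"`,
#'   `"map"` or `"pde"`), `n_states`, `model_states` (columns entering the
#'   regression), `params`, `library`, `xi_true`, `truth` (a `sindy_model`),
#'   `ic_sampler`, `train_ics` and `defaults`.
#' @export
make_example <- function(name) {
  name <- match.arg(name, c("poly1d", "cubic2d", "seir", "lorenz", "burgers"))
  spec <- switch(name,
    poly1d = {
      lib <- feature_library(1, 5)
      xi <- matrix(0, lib$p, 1)
      xi <- set_xi(lib, xi, 1L, 1, 1)
      xi <- set_xi(lib, xi, 3L, 1, -0.2)
      xi <- set_xi(lib, xi, 4L, 1, -0.1)
      list(kind = "ode", n_states = 1L, model_states = 1L,
           params = list(), library = lib, xi_true = xi,
           train_ics = matrix(c(0.5, 2, 4), ncol = 1),
           ic_sampler = function(n) matrix(stats::runif(n, 0.5, 4), ncol = 1),
           defaults = list(n_train = 3L, duration = 4, step = 0.01,
                           noise_sd = 1e-3, valid_duration = 4,
                           n_valid = 100L, mode = "stlsq"))
    },
    cubic2d = {
      lib <- feature_library(2, 6)  # 28 monomials
      xi <- matrix(0, lib$p, 2)
      xi <- set_xi(lib, xi, c(3L, 0L), 1, -0.1)
      xi <- set_xi(lib, xi, c(0L, 3L), 1, 2)
      xi <- set_xi(lib, xi, c(3L, 0L), 2, -2)
      xi <- set_xi(lib, xi, c(0L, 3L), 2, -0.1)
      list(kind = "ode", n_states = 2L, model_states = 1:2,
           params = list(), library = lib, xi_true = xi,
           train_ics = matrix(c(2, 0), ncol = 2),
           ic_sampler = function(n)
             cbind(stats::runif(n, 0.5, 2) * sample(c(-1, 1), n, replace = TRUE),
                   stats::runif(n, 0.5, 2) * sample(c(-1, 1), n, replace = TRUE)),
           defaults = list(n_train = 1L, duration = 10, step = 0.01,
                           noise_sd = 1e-3, valid_duration = 10,
                           n_valid = 100L, mode = "stlsq"))
    },
    seir = {
      lib <- feature_library(3, 2, vars = c("S", "E", "I"))
      # closed population of N = 1000 individuals; additive measurement noise
      # of sd 2.5e-4 is a count-scale model, so states are counts, not
      # fractions (the redundant R update pins gamma = 0.04 per step)
      N <- 1000; beta <- 0.3 / N; sigma <- 0.1; gamma <- 0.04
      xi <- matrix(0, lib$p, 3)
      xi <- set_xi(lib, xi, c(1L, 0L, 0L), 1, 1)          # S
      xi <- set_xi(lib, xi, c(1L, 0L, 1L), 1, -beta)      # -beta S I / contact
      xi <- set_xi(lib, xi, c(0L, 1L, 0L), 2, 1 - sigma)  # (1 - sigma) E
      xi <- set_xi(lib, xi, c(1L, 0L, 1L), 2, beta)       # +beta S I
      xi <- set_xi(lib, xi, c(0L, 1L, 0L), 3, sigma)      # sigma E
      xi <- set_xi(lib, xi, c(0L, 0L, 1L), 3, 1 - gamma)  # (1 - gamma) I
      list(kind = "map", n_states = 4L, model_states = 1:3,
           params = list(beta = beta, sigma = sigma, gamma = gamma,
                         population = N),
           library = lib, xi_true = xi,
           train_ics = matrix(c(996, 3, 1, 0), ncol = 4),
           ic_sampler = function(n) {
             E0 <- stats::runif(n, 1, 10)
             I0 <- stats::runif(n, 1, 10)
             cbind(N - E0 - I0, E0, I0, 0)
           },
           defaults = list(n_train = 1L, duration = 250, step = 1,
                           noise_sd = 2.5e-4, valid_duration = 250,
                           n_valid = 100L, mode = "stlsq"))
    },
    lorenz = {
      lib <- feature_library(3, 2)
      s <- 10; r <- 28; b <- 8 / 3
      xi <- matrix(0, lib$p, 3)
      xi <- set_xi(lib, xi, c(1L, 0L, 0L), 1, -s)
      xi <- set_xi(lib, xi, c(0L, 1L, 0L), 1, s)
      xi <- set_xi(lib, xi, c(1L, 0L, 0L), 2, r)
      xi <- set_xi(lib, xi, c(0L, 1L, 0L), 2, -1)
      xi <- set_xi(lib, xi, c(1L, 0L, 1L), 2, -1)
      xi <- set_xi(lib, xi, c(1L, 1L, 0L), 3, 1)
      xi <- set_xi(lib, xi, c(0L, 0L, 1L), 3, -b)
      list(kind = "ode", n_states = 3L, model_states = 1:3,
           params = list(sigma = s, rho = r, beta = b),
           library = lib, xi_true = xi,
           train_ics = matrix(c(-8, 7, 27), ncol = 3),
           ic_sampler = function(n)
             cbind(stats::runif(n, -15, 15), stats::runif(n, -15, 15),
                   stats::runif(n, 10, 40)),
           defaults = list(n_train = 1L, duration = 10, step = 0.002,
                           noise_sd = 1e-3, valid_duration = 5,
                           valid_step = 0.01, n_valid = 100L, mode = "stlsq"))
    },
    burgers = {
      lib <- pde_library(3, 3)
      nu <- 0.1
      xi <- matrix(0, lib$p, 1)
      xi <- set_xi(lib, xi, 1L, 1, -1, derivative_order = 1L)  # -u u_x
      xi <- set_xi(lib, xi, 0L, 1, nu, derivative_order = 2L)  # +nu u_xx
      grid <- seq(-8, 8, length.out = 101)
      list(kind = "pde", n_states = 1L, model_states = 1L,
           params = list(nu = nu), library = lib, xi_true = xi,
           spatial_grid = grid,
           make_ic = function(amp, center) amp * exp(-(grid - center)^2),
           train_ics = matrix(c(1, -2), ncol = 2),
           ic_sampler = function(n)
             cbind(stats::runif(n, 0.5, 1.5), stats::runif(n, -4, 0)),
           defaults = list(n_train = 1L, duration = 5, step = 0.1,
                           noise_sd = 1e-4, valid_duration = 5,
                           n_valid = 10L, mode = "stridge",
                           dt_internal = 0.02))
    })
  spec$name <- name
  spec$truth <- new_sindy_model(spec$xi_true, term_labels(spec$library),
                                origin = "truth", lambda_used = 0)
  structure(spec, class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("System '%s' (%s, %d states): true model has %d terms\n",
              x$name, x$kind, x$n_states, x$truth$k))
  mode <- switch(x$kind, ode = "derivative", map = "next_state", pde = "pde")
  cat(paste(" ", format_model(x$truth, x$library, mode), collapse = "\n"), "\n")
  invisible(x)
}

# ---- integrators ---------------------------------------------------------

divergence_error <- function(t) {
  structure(class = c("sindy_divergence", "error", "condition"),
            list(message = sprintf("state diverged at t = %g", t), call = NULL,
                 time = t))
}

# Integrate dx/dt = Theta(x) Xi with deSolve::lsoda; stops (as a condition
# carrying the failure time) when any state leaves [-bound, bound].
integrate_poly_ode <- function(E, coefs, x0, times, bound = Inf,
                               rtol = 1e-8, atol = 1e-10) {
  track <- new.env()
  track$t <- times[1]
  rhs <- function(t, y, parms) {
    if (any(!is.finite(y)) || max(abs(y)) > bound) stop(divergence_error(track$t))
    track$t <- t
    list(as.vector(crossprod(monomial_row(E, y), coefs)))
  }
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(y = x0, times = times, func = rhs,
                                    rtol = rtol, atol = atol, maxsteps = 10000)),
    error = function(e) e)
  if (inherits(out, "error"))
    return(list(states = NULL, diverged = TRUE,
                diverge_time = if (!is.null(out$time)) out$time else track$t))
  states <- unname(out[, -1, drop = FALSE])
  if (nrow(states) < length(times) || anyNA(states) ||
      any(!is.finite(states)) || max(abs(states)) > bound) {
    bad <- which(!stats::complete.cases(states) |
                   apply(states, 1, function(r) any(!is.finite(r)) || max(abs(r)) > bound))
    tdiv <- if (length(bad)) times[bad[1]] else times[nrow(states)]
    return(list(states = NULL, diverged = TRUE, diverge_time = tdiv))
  }
  list(states = states, diverged = FALSE, diverge_time = NA_real_)
}

iterate_poly_map <- function(E, coefs, x0, n_steps, bound = Inf) {
  n <- length(x0)
  states <- matrix(NA_real_, n_steps + 1L, n)
  states[1, ] <- x0
  x <- x0
  for (k in seq_len(n_steps)) {
    x <- as.vector(crossprod(monomial_row(E, x), coefs))
    if (any(!is.finite(x)) || max(abs(x)) > bound)
      return(list(states = NULL, diverged = TRUE, diverge_time = k))
    states[k + 1L, ] <- x
  }
  list(states = states, diverged = FALSE, diverge_time = NA_real_)
}

# Right-hand side of a PDE candidate: sum of coef * u^a * d^b u/dx^b fields.
pde_rhs <- function(lib, coefs, u, dx) {
  orders <- vapply(lib$terms, `[[`, 0L, "derivative_order")
  dcache <- list(`0` = u)
  for (b in sort(unique(orders[orders > 0L])))
    dcache[[as.character(b)]] <- fd_derivative(u, dx, b)
  out <- numeric(length(u))
  act <- which(coefs[, 1] != 0)
  for (i in act) {
    tm <- lib$terms[[i]]
    f <- if (tm$exponents[1] > 0L) u^tm$exponents[1] else rep(1, length(u))
    if (tm$derivative_order > 0L)
      f <- f * dcache[[as.character(tm$derivative_order)]]
    out <- out + coefs[i, 1] * f
  }
  out
}

# Fixed-step RK4 method-of-lines stepper for PDE candidates.
integrate_pde <- function(lib, coefs, u0, times, dx, dt_internal, bound = Inf) {
  n_out <- length(times)
  states <- matrix(NA_real_, n_out, length(u0))
  states[1, ] <- u0
  u <- u0
  for (s in seq_len(n_out - 1L)) {
    span <- times[s + 1L] - times[s]
    nsub <- max(1L, ceiling(span / dt_internal))
    h <- span / nsub
    for (sub in seq_len(nsub)) {
      k1 <- pde_rhs(lib, coefs, u, dx)
      k2 <- pde_rhs(lib, coefs, u + h / 2 * k1, dx)
      k3 <- pde_rhs(lib, coefs, u + h / 2 * k2, dx)
      k4 <- pde_rhs(lib, coefs, u + h * k3, dx)
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(u)) || max(abs(u)) > bound)
        return(list(states = NULL, diverged = TRUE,
                    diverge_time = times[s] + sub * h))
    }
    states[s + 1L, ] <- u
  }
  list(states = states, diverged = FALSE, diverge_time = NA_real_)
}

# ---- simulation of truth and candidates ---------------------------------

#' Simulate a ground-truth system and its exact derivatives
#'
#' Integrates the noiseless truth (adaptive `lsoda` with tight tolerances for
#' ODEs, exact iteration for maps, method-of-lines RK4 for the PDE), samples
#' it on the uniform output grid, then adds i.i.d. Gaussian measurement noise
#' to every sampled value. Exact regression targets are computed from the
#' noiseless states: the true right-hand side for ODEs/PDEs, the noiseless
#' next state for maps.
#'
#' @param spec a `system_spec` from [make_example()].
#' @param x0 initial condition (initial field for the PDE; for `burgers` a
#'   length-2 vector `(amplitude, center)` is also accepted).
#' @param duration total simulated time (number of steps for maps).
#' @param step output sampling step.
#' @param seed optional integer seed for the noise realization.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @return list with `times`, `states` (noisy), `clean` (noiseless states),
#'   `derivs` (exact targets; for maps one fewer row than `states`), `x0`.
#' @export
simulate_system <- function(spec, x0, duration, step, seed = NULL,
                            noise_sd = 0) {
  if (step <= 0 || duration < step) stop("need step > 0 and duration >= step")
  n_steps <- round(duration / step)
  times <- (0:n_steps) * step
  if (spec$kind == "ode") {
    E <- exponent_matrix(spec$library)
    res <- integrate_poly_ode(E, spec$xi_true, x0, times)
    if (res$diverged)
      stop(sprintf("truth simulation diverged at t = %g", res$diverge_time))
    clean <- res$states
    derivs <- monomial_columns(E, clean) %*% spec$xi_true
  } else if (spec$kind == "map") {
    clean <- iterate_map_full(spec, x0, n_steps)
    derivs <- clean[-1, spec$model_states, drop = FALSE]
  } else {
    if (length(x0) == 2 && length(spec$spatial_grid) > 2)
      x0 <- spec$make_ic(x0[1], x0[2])
    dt <- spec$defaults$dt_internal
    dx <- check_uniform_grid(spec$spatial_grid)
    res <- integrate_pde(spec$library, spec$xi_true, x0, times, dx, dt)
    if (res$diverged)
      stop(sprintf("truth simulation diverged at t = %g", res$diverge_time))
    clean <- res$states
    derivs <- t(apply(clean, 1, function(u) pde_rhs(spec$library, spec$xi_true, u, dx)))
  }
  if (!is.null(seed)) set.seed(seed)
  states <- clean
  if (noise_sd > 0) states <- states + stats::rnorm(length(states), 0, noise_sd)
  list(times = times, states = states, clean = clean, derivs = derivs, x0 = x0)
}

# Full SEIR-style map step including redundant states (here the R column).
iterate_map_full <- function(spec, x0, n_steps) {
  if (spec$name == "seir") {
    b <- spec$params$beta; sg <- spec$params$sigma; g <- spec$params$gamma
    states <- matrix(NA_real_, n_steps + 1L, 4L)
    states[1, ] <- x0
    x <- x0
    for (k in seq_len(n_steps)) {
      x <- c(x[1] - b * x[1] * x[3],
             x[2] + b * x[1] * x[3] - sg * x[2],
             x[3] + sg * x[2] - g * x[3],
             x[4] + g * x[3])
      states[k + 1L, ] <- x
    }
    states
  } else {
    E <- exponent_matrix(spec$library)
    res <- iterate_poly_map(E, spec$xi_true, x0, n_steps)
    if (res$diverged) stop("truth map iteration diverged")
    res$states
  }
}

#' Simulate a candidate model from an initial condition
#'
#' Integrates (continuous), iterates (map) or steps (PDE, method of lines)
#' the candidate dynamics from `x0` on a uniform time grid. Divergence is
#' data, not an exception: if any state exceeds `divergence_bound` in
#' magnitude or the integrator fails, the result carries a divergence flag
#' and the failure time instead of raising an error.
#'
#' @param model a `sindy_model`.
#' @param lib the `sindy_library` the model is dimensioned to.
#' @param x0 initial state (initial field for PDE libraries).
#' @param duration,step output time grid specification.
#' @param kind `"ode"`, `"map"` or `"pde"`.
#' @param divergence_bound magnitude bound beyond which the trajectory is
#'   flagged divergent (default 1e6).
#' @param spatial_grid uniform spatial grid (PDE only).
#' @param dt_internal internal RK4 step for the PDE stepper.
#' @param rtol,atol ODE integrator tolerances.
#' @return a trajectory record with `x0`, `times`, `states` (`NULL` when
#'   divergent), `diverged` and `diverge_time`.
#' @export
simulate_candidate <- function(model, lib, x0, duration, step,
                               kind = c("ode", "map", "pde"),
                               divergence_bound = 1e6, spatial_grid = NULL,
                               dt_internal = 0.02, rtol = 1e-6, atol = 1e-8) {
  kind <- match.arg(kind)
  n_steps <- round(duration / step)
  times <- (0:n_steps) * step
  res <- if (kind == "ode") {
    integrate_poly_ode(exponent_matrix(lib), model$coefficients, x0, times,
                       bound = divergence_bound, rtol = rtol, atol = atol)
  } else if (kind == "map") {
    iterate_poly_map(exponent_matrix(lib), model$coefficients, x0, n_steps,
                     bound = divergence_bound)
  } else {
    dx <- check_uniform_grid(spatial_grid)
    integrate_pde(lib, model$coefficients, x0, times, dx, dt_internal,
                  bound = divergence_bound)
  }
  new_trajectory(x0, times, res$states, res$diverged, res$diverge_time)
}

#' Generate matched training and validation data for an example system
#'
#' Training trajectories start from the system's documented training initial
#' conditions; validation trajectories start from fresh initial conditions
#' drawn from the system's sampler. Training and validation share duration
#' and sampling step unless `valid_duration` is given. All sampled values
#' (training and validation) carry additive Gaussian noise of standard
#' deviation `noise_sd`; regression targets are exact (computed from the
#' noiseless states).
#'
#' @param spec a `system_spec`.
#' @param n_train,n_valid numbers of training / validation trajectories.
#' @param duration,step output grid; defaults from the spec.
#' @param noise_sd measurement-noise standard deviation; default from the spec.
#' @param seed integer seed controlling initial conditions and noise.
#' @param valid_duration optional distinct validation horizon.
#' @return list with `train` (a `trajectory_set`), `derivs` (list of exact
#'   target matrices, one per training trajectory) and `valid` (a
#'   `trajectory_set`).
#' @export
generate_dataset <- function(spec, n_train = NULL, n_valid = NULL,
                             duration = NULL, step = NULL, noise_sd = NULL,
                             seed = 1L, valid_duration = NULL) {
  d <- spec$defaults
  duration_given <- !is.null(duration)
  if (is.null(n_train)) n_train <- d$n_train
  if (is.null(n_valid)) n_valid <- d$n_valid
  if (is.null(duration)) duration <- d$duration
  if (is.null(step)) step <- d$step
  if (is.null(noise_sd)) noise_sd <- d$noise_sd
  if (is.null(valid_duration)) {
    # validation matches training duration unless the example documents a
    # distinct validation horizon and the training duration was not overridden
    valid_duration <- if (!duration_given && !is.null(d$valid_duration))
      d$valid_duration else duration
  }
  if (n_train < 1 || n_valid < 1) stop("n_train and n_valid must be >= 1")
  set.seed(seed)
  ics <- spec$train_ics
  if (nrow(ics) < n_train)
    ics <- rbind(ics, spec$ic_sampler(n_train - nrow(ics)))
  train <- list(); derivs <- list()
  for (i in seq_len(n_train)) {
    x0 <- ics[i, ]
    sim <- simulate_system(spec, x0, duration, step, noise_sd = noise_sd)
    train[[i]] <- new_trajectory(sim$x0, sim$times, sim$states)
    derivs[[i]] <- sim$derivs
  }
  vics <- spec$ic_sampler(n_valid)
  valid <- vector("list", n_valid)
  vstep <- if (!is.null(d$valid_step)) d$valid_step else step
  for (i in seq_len(n_valid)) {
    sim <- simulate_system(spec, vics[i, ], valid_duration, vstep,
                           noise_sd = noise_sd)
    valid[[i]] <- new_trajectory(sim$x0, sim$times, sim$states)
  }
  list(train = trajectory_set(train, noise_sd, step, "training"),
       derivs = derivs,
       valid = trajectory_set(valid, noise_sd, vstep, "validation"))
}

#' Assemble the regression design and target matrices from training data
#'
#' Stacks the evaluated library over all training trajectories and pairs it
#' with the exact targets. For map systems the design uses states at steps
#' `0..N-1` and the target the (noiseless) states at `1..N`; for PDE systems
#' rows are all (snapshot, grid point) pairs.
#'
#' @param lib a `sindy_library`.
#' @param train training `trajectory_set`.
#' @param derivs list of exact target matrices from [generate_dataset()].
#' @param kind `"ode"`, `"map"` or `"pde"`.
#' @param model_states columns of the state entering the model (e.g. S, E, I
#'   for the SEIR example).
#' @param spatial_grid uniform spatial grid (PDE only).
#' @return list with `design` (m x p) and `target` (m x n_model).
#' @export
build_regression_data <- function(lib, train, derivs,
                                  kind = c("ode", "map", "pde"),
                                  model_states = NULL, spatial_grid = NULL) {
  kind <- match.arg(kind)
  designs <- list(); targets <- list()
  for (i in seq_along(train$trajectories)) {
    st <- train$trajectories[[i]]$states
    dv <- derivs[[i]]
    if (kind == "pde") {
      designs[[i]] <- evaluate_library(lib, st, spatial_grid)
      targets[[i]] <- matrix(as.vector(t(dv)), ncol = 1)
    } else {
      if (!is.null(model_states)) st <- st[, model_states, drop = FALSE]
      if (kind == "map") st <- st[-nrow(st), , drop = FALSE]
      designs[[i]] <- evaluate_library(lib, st)
      targets[[i]] <- dv
    }
  }
  list(design = do.call(rbind, designs), target = do.call(rbind, targets))
}
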