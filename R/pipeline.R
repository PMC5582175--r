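#' Configuration for an end-to-end model-selection run
#'
#' Bundles every knob of the selection pipeline. A run is reproducible from
#' its configuration alone: `seed` drives the initial conditions and every
#' noise realization.
#'
#' @param system name of a worked example (see [make_example()]), or `NULL`
#'   when `train_file`/`valid_file` provide the data.
#' @param mode candidate-generation mode: `"stlsq"` (threshold sweep),
#'   `"exhaustive"` (all non-empty term subsets) or `"stridge"` (ridge sweep,
#'   for PDE data). Defaults to the example's documented mode.
#' @param n_train,n_valid numbers of training and validation trajectories
#'   (defaults from the example; `n_valid` defaults to 100).
#' @param duration,step,valid_duration sampling design overrides.
#' @param noise_sd measurement-noise standard deviation override.
#' @param thresholds optional explicit sparsity grid for sweep modes.
#' @param ridge_penalty,stridge_iterations STRidge controls.
#' @param stridge_tol base tolerance of the STRidge sweep (default 0.1).
#' @param max_exhaustive_p library-size cap for exhaustive mode.
#' @param include_redundant keep redundant state columns (e.g. the SEIR `R`
#'   compartment) in the library; reproduces the known failure mode.
#' @param error_convention,error_squared validation-error conventions.
#' @param divergence_bound state-magnitude bound for flagging divergence.
#' @param seed integer seed.
#' @param train_file,valid_file optional trajectory files (see
#'   [load_trajectories()]) used instead of synthetic generation; requires
#'   `library_spec`.
#' @param library_spec list `(n_states, max_degree)` for file-based runs.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(system = NULL,
                             mode = NULL,
                             n_train = NULL, n_valid = NULL,
                             duration = NULL, step = NULL,
                             valid_duration = NULL,
                             noise_sd = NULL,
                             thresholds = NULL,
                             ridge_penalty = 1e-5,
                             stridge_iterations = 50L,
                             stridge_tol = 0.1,
                             max_exhaustive_p = 20L,
                             include_redundant = FALSE,
                             error_convention = "mean",
                             error_squared = FALSE,
                             divergence_bound = 1e6,
                             seed = 1L,
                             train_file = NULL, valid_file = NULL,
                             library_spec = NULL) {
  if (is.null(system) && (is.null(train_file) || is.null(valid_file)))
    stop("either a system name or train_file + valid_file must be given")
  if (!is.null(n_valid) && n_valid < 1) stop("n_valid must be >= 1")
  if (!is.null(n_train) && n_train < 1) stop("n_train must be >= 1")
  cfg <- list(system = system, mode = mode, n_train = n_train,
              n_valid = n_valid, duration = duration, step = step,
              valid_duration = valid_duration, noise_sd = noise_sd,
              thresholds = thresholds, ridge_penalty = ridge_penalty,
              stridge_iterations = stridge_iterations,
              stridge_tol = stridge_tol,
              max_exhaustive_p = max_exhaustive_p,
              include_redundant = include_redundant,
              error_convention = error_convention,
              error_squared = error_squared,
              divergence_bound = divergence_bound, seed = as.integer(seed),
              train_file = train_file, valid_file = valid_file,
              library_spec = library_spec)
  structure(cfg, class = "selection_config")
}

stridge_tol_grid <- function(base_tol) {
  sort(unique(c(base_tol * 10^seq(-1, 1.5, length.out = 40))))
}

#' Run the full selection pipeline
#'
#' Executes the end-to-end procedure: (1) generate (or load) training data
#' with exact regression targets and a validation trajectory set; (2) build
#' the feature library and evaluate it on the training measurements;
#' (3) generate candidate models with the configured sparse regressor;
#' (4) simulate every candidate from each validation initial condition;
#' (5) compute per-trajectory errors; (6) AICc-rank and classify every
#' candidate as strong / weak / borderline / no support (or unstable).
#'
#' @param config a `selection_config`.
#' @param quiet suppress per-stage progress messages.
#' @return object of class `selection_report`: `scores` (ranked table),
#'   `models`, `selected` (the `delta = 0` model, or `NULL` when every
#'   candidate is unstable), `selected_row`, `counts` (category counts),
#'   `library`, `truth` (generator truth when synthetic), `truth_recovered`,
#'   `config` and `data`.
#' @export
run_selection <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "selection_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$system)) {
    spec <- make_example(config$system)
    kind <- spec$kind
    lib <- spec$library
    data <- generate_dataset(spec,
                             n_train = config$n_train,
                             n_valid = config$n_valid,
                             duration = config$duration,
                             step = config$step,
                             noise_sd = config$noise_sd,
                             seed = config$seed,
                             valid_duration = config$valid_duration)
    model_states <- if (config$include_redundant) seq_len(spec$n_states)
                    else spec$model_states
    if (config$include_redundant && spec$kind == "map") {
      lib <- feature_library(spec$n_states, 2,
                             vars = c(lib$vars, "R")[seq_len(spec$n_states)])
      # with R included, targets are the noiseless next states of all columns
      data$derivs <- lapply(seq_along(data$derivs), function(i) {
        tr <- data$train$trajectories[[i]]
        sim <- simulate_system(spec, tr$x0, max(tr$times), data$train$step)
        sim$clean[-1, , drop = FALSE]
      })
    }
    spatial_grid <- spec$spatial_grid
    dt_internal <- if (!is.null(spec$defaults$dt_internal))
      spec$defaults$dt_internal else 0.02
    truth <- spec$truth
  } else {
    if (is.null(config$library_spec))
      stop("library_spec is required for file-based runs")
    kind <- "ode"
    lib <- feature_library(config$library_spec$n_states,
                           config$library_spec$max_degree)
    train <- load_trajectories(config$train_file)
    valid <- load_trajectories(config$valid_file)
    derivs <- lapply(train$trajectories, function(tr)
      numeric_derivatives(tr$states, tr$times))
    data <- list(train = train, derivs = derivs, valid = valid)
    model_states <- seq_len(config$library_spec$n_states)
    spatial_grid <- NULL; dt_internal <- 0.02
    truth <- NULL; spec <- NULL
  }
  say("data: %d training / %d validation trajectories",
      length(data$train$trajectories), length(data$valid$trajectories))

  reg <- build_regression_data(lib, data$train, data$derivs, kind,
                               model_states = model_states,
                               spatial_grid = spatial_grid)
  say("library: %d terms, design %d x %d", lib$p, nrow(reg$design), lib$p)

  mode <- config$mode
  if (is.null(mode) && !is.null(spec)) mode <- spec$defaults$mode
  if (is.null(mode)) mode <- "stlsq"
  models <- switch(mode,
    stlsq = sweep_thresholds(reg$design, reg$target, grid = config$thresholds),
    stridge = sweep_thresholds(reg$design, reg$target,
                               grid = if (!is.null(config$thresholds))
                                 config$thresholds
                               else stridge_tol_grid(config$stridge_tol),
                               method = "stridge",
                               ridge_penalty = config$ridge_penalty,
                               iterations = config$stridge_iterations),
    exhaustive = exhaustive_fit(reg$design, reg$target,
                                max_p = config$max_exhaustive_p),
    stop("unknown mode: ", mode))
  say("candidates: %d models (%s)", length(models), mode)

  scored <- score_models(models, lib, data$valid, kind,
                         model_states = model_states,
                         divergence_bound = config$divergence_bound,
                         spatial_grid = spatial_grid,
                         dt_internal = dt_internal,
                         convention = config$error_convention,
                         squared = config$error_squared)
  ranked <- rank_and_classify(scored$table)
  say("scored %d candidates against %d validation trajectories",
      nrow(ranked), ranked$m_obs[1])

  counts <- table(factor(ranked$category,
                         levels = c("strong", "borderline", "weak", "none",
                                    "unstable")))
  all_unstable <- all(ranked$unstable)
  if (all_unstable)
    warning("every candidate model diverged on validation data; no selection made")
  selected <- if (all_unstable) NULL else models[[ranked$model_id[1]]]
  truth_recovered <- if (!is.null(truth) && !is.null(selected))
    identical(selected$support[, , drop = FALSE] != 0,
              truth$support[, , drop = FALSE] != 0)
  else NA

  structure(list(scores = ranked, models = models, selected = selected,
                 selected_row = if (all_unstable) NULL else ranked[1, ],
                 counts = as.list(counts), library = lib, truth = truth,
                 truth_recovered = truth_recovered, kind = kind,
                 model_states = model_states,
                 config = config, data = data,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection report: %d candidates, %d validation trajectories\n",
              nrow(x$scores), x$scores$m_obs[1]))
  cat(sprintf("  support counts: strong %d | borderline %d | weak %d | none %d | unstable %d\n",
              x$counts$strong, x$counts$borderline, x$counts$weak,
              x$counts$none, x$counts$unstable))
  if (is.null(x$selected)) {
    cat("  no selection: every candidate diverged on validation data\n")
  } else {
    mode <- switch(x$kind, ode = "derivative", map = "next_state", pde = "pde")
    cat(sprintf("  selected model (delta = 0, k = %d):\n", x$selected$k))
    cat(paste("   ", format_model(x$selected, x$library, mode),
              collapse = "\n"), "\n")
    if (!is.na(x$truth_recovered))
      cat(sprintf("  true support recovered: %s\n", x$truth_recovered))
  }
  top <- utils::head(x$scores[, c("k", "terms", "aicc", "delta", "category")], 8)
  print(top, row.names = FALSE)
  invisible(x)
}

# Central difference in time for file-based data without derivative columns
# (2nd-order one-sided stencils at the series endpoints).
numeric_derivatives <- function(states, times) {
  h <- diff(times)[1]
  n <- nrow(states)
  d <- states
  d[2:(n - 1), ] <- (states[3:n, , drop = FALSE] -
                       states[1:(n - 2), , drop = FALSE]) / (2 * h)
  d[1, ] <- (-3 * states[1, ] + 4 * states[2, ] - states[3, ]) / (2 * h)
  d[n, ] <- (3 * states[n, ] - 4 * states[n - 1, ] + states[n - 2, ]) / (2 * h)
  d
}

#' Sensitivity of the selection to noise, validation-set size or horizon
#'
#' Re-runs [run_selection()] for every value of the chosen axis and every
#' replicate (with fresh seeded noise), recording whether the generator's
#' true support entered the candidate set, its relative AICc and rank, and
#' how many incorrect models received support (`delta <= 7`).
#'
#' @param config base `selection_config` (must name a synthetic system).
#' @param axis `"noise"`, `"n_valid"` or `"horizon"`.
#' @param values values the axis takes.
#' @param replicates replicate runs per value.
#' @param seed integer seed from which per-run seeds are drawn.
#' @return data frame with one row per (value, replicate): `axis`, `value`,
#'   `replicate`, `seed`, `truth_in_candidates`, `truth_delta`, `truth_rank`,
#'   `n_supported_incorrect`, `selected_k`, `truth_selected`.
#' @export
sensitivity_experiment <- function(config, axis = c("noise", "n_valid", "horizon"),
                                   values, replicates = 1L, seed = 1L) {
  axis <- match.arg(axis)
  if (!length(values)) stop("values must be non-empty")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(config$system)) stop("sensitivity runs require a synthetic system")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, length(values) * replicates)
  spec <- make_example(config$system)
  truth_key <- support_key(spec$truth)
  rows <- list(); idx <- 0L
  for (vi in seq_along(values)) {
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      cfg <- config
      cfg$seed <- run_seeds[idx]
      if (axis == "noise") cfg$noise_sd <- values[vi]
      if (axis == "n_valid") cfg$n_valid <- as.integer(values[vi])
      if (axis == "horizon") cfg$valid_duration <- values[vi]
      rep_out <- run_selection(cfg)
      keys <- vapply(rep_out$models, support_key, "")
      truth_pos <- match(truth_key, keys)
      truth_in <- !is.na(truth_pos)
      truth_delta <- if (truth_in)
        rep_out$scores$delta[match(truth_pos, rep_out$scores$model_id)] else NA_real_
      truth_rank <- if (truth_in)
        which(rep_out$scores$model_id == truth_pos) else NA_integer_
      supported <- rep_out$scores$delta <= 7
      n_bad <- sum(supported & rep_out$scores$model_id !=
                     (if (truth_in) truth_pos else -1L))
      rows[[idx]] <- data.frame(
        axis = axis, value = values[vi], replicate = r, seed = cfg$seed,
        truth_in_candidates = truth_in, truth_delta = truth_delta,
        truth_rank = truth_rank, n_supported_incorrect = n_bad,
        selected_k = if (is.null(rep_out$selected)) NA_integer_
                     else rep_out$selected$k,
        truth_selected = isTRUE(rep_out$truth_recovered),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
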