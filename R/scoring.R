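#' Representative error of a simulated trajectory against an observed one
#'
#' Computes the average absolute deviation between a candidate model's
#' simulated trajectory and the observed validation trajectory, over all time
#' points and state components. The default convention is the mean; setting
#' `convention = "sum"` gives the literal sum of absolute deviations and
#' `squared = TRUE` squares the deviations first. Because information-criteria
#' differences are invariant under a common positive rescaling of all
#' per-trajectory errors, the mean-vs-sum choice cannot change any ranking.
#' A divergent simulation has error `+Inf`.
#'
#' @param simulated trajectory record from [simulate_candidate()].
#' @param observed trajectory record with matching time grid.
#' @param convention `"mean"` (default) or `"sum"`.
#' @param squared square deviations before aggregating (default `FALSE`).
#' @return non-negative scalar (possibly `Inf`).
#' @export
trajectory_error <- function(simulated, observed, convention = c("mean", "sum"),
                             squared = FALSE) {
  convention <- match.arg(convention)
  if (isTRUE(simulated$diverged)) return(Inf)
  if (length(simulated$times) != length(observed$times) ||
      max(abs(simulated$times - observed$times)) > 1e-8)
    stop("time grids of simulated and observed trajectories do not match")
  if (!identical(dim(simulated$states), dim(observed$states)))
    stop("state dimensions of simulated and observed trajectories do not match")
  dev <- abs(observed$states - simulated$states)
  if (squared) dev <- dev^2
  if (convention == "mean") mean(dev) else sum(dev)
}

#' AIC from per-trajectory validation errors
#'
#' Uses the residual-sum-of-squares surrogate with one complete validation
#' trajectory counted as one observation:
#' `AIC = m * log(sum(e_avg) / m) + 2k`, where `m = length(e_avg)` and `k` is
#' the candidate's number of free parameters (total nonzero coefficients).
#' Any infinite entry (a divergent validation simulation) gives `+Inf`;
#' all-zero errors give `-Inf` (a degenerate perfect fit, only possible on a
#' noiseless self-fit).
#'
#' @param e_avg vector of per-trajectory representative errors (>= 0).
#' @param k number of free parameters.
#' @return AIC value.
#' @export
aic_from_errors <- function(e_avg, k) {
  if (!length(e_avg)) stop("e_avg is empty")
  if (any(e_avg < 0)) stop("errors must be >= 0")
  m <- length(e_avg)
  if (any(is.infinite(e_avg))) return(Inf)
  m * log(sum(e_avg) / m) + 2 * k
}

#' Finite-sample (corrected) AIC
#'
#' `AICc = AIC + 2 (k + 1) (k + 2) / (m - k - 2)` when `m - k - 2 > 0`;
#' otherwise the model cannot be supported at this number of observations and
#' the score is `+Inf` (with a warning).
#'
#' @param aic AIC value.
#' @param k number of free parameters.
#' @param m number of observations (validation trajectories).
#' @return corrected AIC.
#' @export
aicc <- function(aic, k, m) {
  if (m < 1) stop("m must be >= 1")
  if (k < 0) stop("k must be >= 0")
  if (m - k - 2 <= 0) {
    warning(sprintf("AICc undefined for k = %d at m = %d observations", k, m))
    return(Inf)
  }
  aic + 2 * (k + 1) * (k + 2) / (m - k - 2)
}

#' BIC from per-trajectory validation errors
#'
#' Standard Bayes information criterion with the same error surrogate as
#' [aic_from_errors()]: `BIC = m * log(sum(e_avg) / m) + k * log(m)`.
#'
#' @inheritParams aic_from_errors
#' @return BIC value.
#' @export
bic_from_errors <- function(e_avg, k) {
  if (!length(e_avg)) stop("e_avg is empty")
  if (any(e_avg < 0)) stop("errors must be >= 0")
  m <- length(e_avg)
  if (any(is.infinite(e_avg))) return(Inf)
  m * log(sum(e_avg) / m) + k * log(m)
}

classify_delta <- function(delta, unstable) {
  ifelse(unstable, "unstable",
    ifelse(delta <= 2, "strong",
      ifelse(delta < 4, "borderline",
        ifelse(delta <= 7, "weak",
          ifelse(delta < 10, "borderline", "none")))))
}

#' Score candidate models against a validation trajectory set
#'
#' Simulates each candidate from every validation initial condition on the
#' validation time grid, computes the per-trajectory representative errors,
#' and evaluates AIC, AICc and BIC with one validation trajectory counted as
#' one observation.
#'
#' @param models list of `sindy_model` candidates.
#' @param lib the `sindy_library` they are dimensioned to.
#' @param valid validation `trajectory_set`.
#' @param kind `"ode"`, `"map"` or `"pde"`.
#' @param model_states observed state columns entering the model.
#' @param divergence_bound magnitude bound for flagging divergence.
#' @param spatial_grid,dt_internal PDE stepping controls.
#' @param convention,squared error conventions (see [trajectory_error()]).
#' @param rtol,atol validation ODE integrator tolerances.
#' @return list with `table` (one row per model: `model_id`, `origin`,
#'   `lambda_used`, `k`, `terms`, `aic`, `aicc`, `bic`, `unstable`,
#'   `n_diverged`, `mean_error`, `m_obs`) and `e_avg` (matrix of
#'   per-trajectory errors, models x trajectories).
#' @export
score_models <- function(models, lib, valid, kind = c("ode", "map", "pde"),
                         model_states = NULL, divergence_bound = 1e6,
                         spatial_grid = NULL, dt_internal = 0.02,
                         convention = "mean", squared = FALSE,
                         rtol = 1e-6, atol = 1e-8) {
  kind <- match.arg(kind)
  n_mod <- length(models)
  n_val <- length(valid$trajectories)
  if (!n_mod) stop("no candidate models to score")
  duration <- max(valid$trajectories[[1]]$times)
  step <- valid$step
  errs <- matrix(NA_real_, n_mod, n_val)
  diverged <- matrix(FALSE, n_mod, n_val)
  for (i in seq_len(n_mod)) {
    for (v in seq_len(n_val)) {
      obs <- valid$trajectories[[v]]
      x0 <- obs$x0
      states <- obs$states
      if (!is.null(model_states) && kind != "pde") {
        x0 <- x0[model_states]
        states <- states[, model_states, drop = FALSE]
      }
      sim <- simulate_candidate(models[[i]], lib, x0, duration, step, kind,
                                divergence_bound = divergence_bound,
                                spatial_grid = spatial_grid,
                                dt_internal = dt_internal,
                                rtol = rtol, atol = atol)
      obs_sub <- list(times = obs$times, states = states)
      errs[i, v] <- trajectory_error(sim, obs_sub, convention, squared)
      diverged[i, v] <- sim$diverged
    }
  }
  k <- vapply(models, `[[`, 0L, "k")
  aic <- vapply(seq_len(n_mod), function(i) aic_from_errors(errs[i, ], k[i]), 0)
  aiccs <- suppressWarnings(
    vapply(seq_len(n_mod), function(i) aicc(aic[i], k[i], n_val), 0))
  bic <- vapply(seq_len(n_mod), function(i) bic_from_errors(errs[i, ], k[i]), 0)
  terms <- vapply(seq_len(n_mod), function(i) {
    act <- which(rowSums(models[[i]]$support) > 0)
    paste(rownames(models[[i]]$coefficients)[act], collapse = "+")
  }, "")
  tab <- data.frame(
    model_id = seq_len(n_mod),
    origin = vapply(models, `[[`, "", "origin"),
    lambda_used = vapply(models, `[[`, 0, "lambda_used"),
    k = k, terms = terms, aic = aic, aicc = aiccs, bic = bic,
    unstable = rowSums(diverged) > 0,
    n_diverged = rowSums(diverged),
    mean_error = rowMeans(errs),
    m_obs = n_val,
    stringsAsFactors = FALSE)
  list(table = tab, e_avg = errs)
}

#' Rank scored models by relative AICc and classify their support
#'
#' Computes `delta = AICc - min(AICc)` over the compared set and assigns
#' support categories: `strong` for `delta <= 2`, `weak` for
#' `4 <= delta <= 7`, `none` for `delta >= 10`, `borderline` in the gaps
#' `(2, 4)` and `(7, 10)`, and `unstable` when any validation simulation of
#' the model diverged. The output is sorted by `(delta, k)` ascending, ties
#' broken by term labels.
#'
#' @param scores the `table` element of [score_models()] (or a data frame with
#'   columns `aicc`, `k`, `terms`, `unstable` and `m_obs`).
#' @return the same data frame with `delta` and `category` filled, sorted.
#' @export
rank_and_classify <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores) && !is.null(scores$table))
    scores <- scores$table
  if (!nrow(scores)) stop("no scores to rank")
  if (length(unique(scores$m_obs)) != 1L)
    stop("models scored against different numbers of observations cannot be compared")
  amin <- suppressWarnings(min(scores$aicc))
  if (amin == -Inf) {
    # degenerate perfect fits rank first
    scores$delta <- ifelse(scores$aicc == -Inf, 0, Inf)
  } else if (!is.finite(amin)) {
    scores$delta <- rep(Inf, nrow(scores))
  } else {
    scores$delta <- scores$aicc - amin
  }
  scores$category <- classify_delta(scores$delta, scores$unstable)
  scores[order(scores$delta, scores$k, scores$terms), , drop = FALSE]
}
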