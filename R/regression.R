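# Minimum-norm least-squares solution via SVD (used when the restricted
# design is rank deficient).
pinv_solve <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!any(keep)) return(rep(0, ncol(A)))
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

# Least squares restricted to a per-equation support mask.
# support: p x n_states logical. Returns coefficients (zero off support)
# and whether any restricted system was rank deficient.
restricted_lsq <- function(design, target, support) {
  p <- ncol(design); nst <- ncol(target)
  coefs <- matrix(0, p, nst)
  deficient <- FALSE
  for (j in seq_len(nst)) {
    act <- which(support[, j])
    if (!length(act)) next
    As <- design[, act, drop = FALSE]
    qrA <- qr(As)
    if (qrA$rank < length(act)) {
      deficient <- TRUE
      coefs[act, j] <- pinv_solve(As, target[, j])
    } else {
      coefs[act, j] <- qr.coef(qrA, target[, j])
    }
  }
  list(coefficients = coefs, rank_deficient = deficient)
}

ridge_restricted <- function(design, target, support, lam) {
  p <- ncol(design); nst <- ncol(target)
  coefs <- matrix(0, p, nst)
  deficient <- FALSE
  for (j in seq_len(nst)) {
    act <- which(support[, j])
    if (!length(act)) next
    As <- design[, act, drop = FALSE]
    G <- crossprod(As) + lam * diag(length(act))
    sol <- tryCatch(solve(G, crossprod(As, target[, j])), error = function(e) NULL)
    if (is.null(sol)) {
      deficient <- TRUE
      sol <- pinv_solve(As, target[, j])
    }
    coefs[act, j] <- sol
  }
  list(coefficients = coefs, rank_deficient = deficient)
}

new_sindy_model <- function(coefficients, labels, origin, lambda_used,
                            rank_deficient = FALSE) {
  support <- coefficients != 0
  rownames(coefficients) <- labels
  structure(list(coefficients = coefficients,
                 support = support,
                 k = sum(support),
                 origin = origin,
                 lambda_used = lambda_used,
                 rank_deficient = rank_deficient),
            class = "sindy_model")
}

support_key <- function(model) paste(as.integer(model$support), collapse = "")

#' Sequential thresholded least squares (STLSQ)
#'
#' Alternates between least-squares fits on the current support and zeroing
#' every coefficient whose magnitude falls below `threshold`, until the
#' support is unchanged between iterations (or `max_iter` is reached). The
#' returned coefficients are the restricted least-squares solution on the
#' converged support; an all-zero model is a legal result. One threshold is
#' shared across all state equations, but supports are per equation.
#'
#' @param design design matrix from [evaluate_library()] (m x p).
#' @param target matrix of regression targets (m x n_states): time derivatives
#'   for continuous systems or next states for discrete maps.
#' @param threshold sparsity threshold (>= 0); `0` gives ordinary least squares.
#' @param max_iter iteration cap (default 25).
#' @return a `sindy_model` with elements `coefficients` (p x n_states, exactly
#'   zero off support), `support`, `k` (total nonzero coefficients across all
#'   equations), `origin`, `lambda_used` and `rank_deficient`.
#' @export
stlsq <- function(design, target, threshold, max_iter = 25L) {
  target <- as.matrix(target)
  if (threshold < 0) stop("threshold must be >= 0")
  if (nrow(design) != nrow(target)) stop("design/target row mismatch")
  if (anyNA(design) || anyNA(target)) stop("design/target contain NA")
  p <- ncol(design); nst <- ncol(target)
  support <- matrix(TRUE, p, nst)
  fit <- restricted_lsq(design, target, support)
  for (it in seq_len(max_iter)) {
    new_support <- support & (abs(fit$coefficients) >= threshold) &
      (fit$coefficients != 0)
    if (all(new_support == support)) break
    support <- new_support
    fit <- restricted_lsq(design, target, support)
  }
  support <- (abs(fit$coefficients) >= threshold) & (fit$coefficients != 0)
  fit <- restricted_lsq(design, target, support)
  new_sindy_model(fit$coefficients * support, colnames(design),
                  origin = "stlsq", lambda_used = threshold,
                  rank_deficient = fit$rank_deficient)
}

#' Sequential thresholded ridge regression (STRidge)
#'
#' Variant of [stlsq()] used for PDE discovery: each refit during the
#' iteration solves a ridge-regularized least squares on the current support,
#' thresholding at `tol`, for at most `iterations` rounds. The final
#' coefficients are an unregularized restricted least-squares fit on the
#' converged support, so reported coefficients carry no ridge bias.
#'
#' @inheritParams stlsq
#' @param ridge_penalty ridge penalty `lambda >= 0`; `0` reduces STRidge to
#'   [stlsq()] with `threshold = tol`.
#' @param tol sparsity threshold applied to the ridge coefficients.
#' @param iterations iteration cap (default 50).
#' @return a `sindy_model` with `origin = "stridge"`.
#' @export
stridge <- function(design, target, ridge_penalty, tol, iterations = 50L) {
  target <- as.matrix(target)
  if (ridge_penalty < 0) stop("ridge_penalty must be >= 0")
  if (iterations < 1) stop("iterations must be >= 1")
  p <- ncol(design); nst <- ncol(target)
  support <- matrix(TRUE, p, nst)
  fit <- ridge_restricted(design, target, support, ridge_penalty)
  for (it in seq_len(iterations)) {
    new_support <- support & (abs(fit$coefficients) >= tol) &
      (fit$coefficients != 0)
    if (all(new_support == support)) break
    support <- new_support
    fit <- ridge_restricted(design, target, support, ridge_penalty)
  }
  support <- (abs(fit$coefficients) >= tol) & (fit$coefficients != 0)
  final <- restricted_lsq(design, target, support)
  new_sindy_model(final$coefficients * support, colnames(design),
                  origin = "stridge", lambda_used = tol,
                  rank_deficient = final$rank_deficient)
}

#' Default sparsity-threshold grid
#'
#' Log-spaced grid of `n` thresholds spanning `[1e-5, 2]` times the largest
#' ordinary-least-squares coefficient magnitude, which brackets both the
#' spurious-coefficient floor and the largest genuine coefficient.
#'
#' @inheritParams stlsq
#' @param n number of grid values.
#' @return ascending numeric vector of thresholds.
#' @export
default_threshold_grid <- function(design, target, n = 40L) {
  ols <- restricted_lsq(design, as.matrix(target),
                        matrix(TRUE, ncol(design), ncol(as.matrix(target))))
  scale <- max(abs(ols$coefficients))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  10^seq(log10(1e-5), log10(2), length.out = n) * scale
}

#' Sweep the sparsity threshold to generate a candidate-model set
#'
#' Runs [stlsq()] (or [stridge()]) for each grid value, deduplicates models
#' with identical support (keeping the first, i.e. the smallest producing
#' threshold) and returns the candidates sorted by ascending term count `k`.
#' The all-zero model is retained if produced.
#'
#' @inheritParams stlsq
#' @param grid ascending non-negative vector of thresholds; defaults to
#'   [default_threshold_grid()].
#' @param method `"stlsq"` (default) or `"stridge"`.
#' @param ridge_penalty,iterations passed to [stridge()] when
#'   `method = "stridge"`.
#' @return list of `sindy_model` objects sorted by ascending `k`.
#' @export
sweep_thresholds <- function(design, target, grid = NULL,
                             method = c("stlsq", "stridge"),
                             ridge_penalty = 1e-5, iterations = 50L) {
  method <- match.arg(method)
  target <- as.matrix(target)
  if (is.null(grid)) grid <- default_threshold_grid(design, target)
  if (!length(grid)) stop("grid must be non-empty")
  if (any(grid < 0)) stop("grid values must be >= 0")
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  models <- list(); seen <- character()
  for (g in grid) {
    mod <- if (method == "stlsq") stlsq(design, target, g)
           else stridge(design, target, ridge_penalty, g, iterations)
    key <- support_key(mod)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      models[[length(models) + 1L]] <- mod
    }
  }
  models[order(vapply(models, `[[`, 0L, "k"))]
}

#' Exhaustively fit every non-empty subset of library terms
#'
#' One restricted least-squares fit per non-empty subset of the `p` library
#' terms; the subset of active terms is shared across all state equations, so
#' a "model" is one set of active terms for the whole system. Refuses to run
#' when `p` exceeds `max_p` since the number of fits is `2^p - 1`.
#'
#' @inheritParams stlsq
#' @param max_p largest library size accepted (default 20).
#' @return list of `2^p - 1` `sindy_model` objects with `origin = "exhaustive"`.
#' @export
exhaustive_fit <- function(design, target, max_p = 20L) {
  target <- as.matrix(target)
  p <- ncol(design); nst <- ncol(target)
  if (p > max_p)
    stop(sprintf("library has %d terms: %s candidate models exceed max_p = %d",
                 p, format(count_model_space(p), big.mark = ","), max_p))
  n_models <- as.integer(2^p - 1)
  models <- vector("list", n_models)
  bits <- bitwShiftL(1L, 0:(p - 1L))
  for (s in seq_len(n_models)) {
    act <- which(bitwAnd(s, bits) != 0L)
    support <- matrix(FALSE, p, nst)
    support[act, ] <- TRUE
    fit <- restricted_lsq(design, target, support)
    models[[s]] <- new_sindy_model(fit$coefficients, colnames(design),
                                   origin = "exhaustive", lambda_used = 0,
                                   rank_deficient = fit$rank_deficient)
  }
  models
}

#' Format a candidate model as readable equations
#'
#' @param model a `sindy_model`.
#' @param lib the `sindy_library` it was fit against.
#' @param mode `"derivative"` (continuous), `"next_state"` (map) or `"pde"`.
#' @param digits coefficient digits.
#' @return character vector, one equation per state variable.
#' @export
format_model <- function(model, lib, mode = "derivative", digits = 4) {
  labels <- term_labels(lib)
  vars <- lib$vars
  nst <- ncol(model$coefficients)
  out <- character(nst)
  for (j in seq_len(nst)) {
    act <- which(model$support[, j])
    lhs <- switch(mode,
                  derivative = paste0(vars[j], "'"),
                  next_state = paste0(vars[j], "[k+1]"),
                  pde = "u_t")
    if (!length(act)) { out[j] <- paste(lhs, "= 0"); next }
    pieces <- vapply(act, function(i) {
      co <- model$coefficients[i, j]
      term <- if (labels[i] == "1") "" else paste0("*", labels[i])
      paste0(ifelse(co < 0, "- ", "+ "), format(abs(co), digits = digits), term)
    }, "")
    rhs <- paste(pieces, collapse = " ")
    rhs <- sub("^\\+ ", "", rhs)
    out[j] <- paste(lhs, "=", rhs)
  }
  out
}

#' @export
print.sindy_model <- function(x, ...) {
  cat(sprintf("Candidate model (%s, lambda = %g): k = %d term(s)%s\n",
              x$origin, x$lambda_used, x$k,
              if (x$rank_deficient) " [rank deficient: minimum-norm fit]" else ""))
  act <- which(rowSums(x$support) > 0)
  if (length(act)) {
    for (i in act) {
      cat(sprintf("  %-12s %s\n", rownames(x$coefficients)[i],
                  paste(format(x$coefficients[i, ], digits = 4), collapse = "  ")))
    }
  } else cat("  (all-zero model)\n")
  invisible(x)
}
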