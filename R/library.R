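# Default state-variable names used in term labels.
state_names <- function(n) {
  if (n == 1L) "x"
  else if (n == 2L) c("x", "y")
  else if (n == 3L) c("x", "y", "z")
  else paste0("x", seq_len(n))
}

poly_label <- function(exponents, vars) {
  active <- which(exponents > 0L)
  if (!length(active)) return("1")
  paste(vapply(active, function(j) {
    if (exponents[j] == 1L) vars[j] else paste0(vars[j], "^", exponents[j])
  }, ""), collapse = "*")
}

pde_label <- function(a, b) {
  upart <- if (a == 0L) "" else if (a == 1L) "u" else paste0("u^", a)
  dpart <- if (b == 0L) "" else paste0("u_", strrep("x", b))
  if (upart == "" && dpart == "") "1"
  else if (dpart == "") upart
  else if (upart == "") dpart
  else paste0(upart, "*", dpart)
}

# All monomial exponent vectors for n variables, total degree <= d,
# graded lexicographic order (degree ascending, then earlier variables first).
enumerate_monomials <- function(n, d) {
  grid <- as.matrix(expand.grid(rep(list(0:d), n)))
  colnames(grid) <- NULL
  grid <- grid[rowSums(grid) <= d, , drop = FALSE]
  deg <- rowSums(grid)
  ord <- do.call(order, c(list(deg), lapply(seq_len(n), function(j) -grid[, j])))
  grid[ord, , drop = FALSE]
}

new_feature_library <- function(terms, n_states, type, vars) {
  structure(list(terms = terms, n_states = n_states, p = length(terms),
                 type = type, vars = vars),
            class = "sindy_library")
}

#' Build a polynomial feature library
#'
#' Enumerates all monomials in `n_states` state variables up to total degree
#' `max_degree`, including the constant term. Terms are ordered graded
#' lexicographically (by total degree, then by exponent of the first variable,
#' and so on), so the library is deterministic. The number of terms is
#' `choose(n_states + max_degree, max_degree)`.
#'
#' @param n_states number of state variables (>= 1).
#' @param max_degree maximum total polynomial degree (>= 0).
#' @param vars optional character vector of variable names used in term labels;
#'   defaults to `x`, `x, y`, `x, y, z` or `x1..xn`.
#' @return an object of class `sindy_library` with elements `terms` (list of
#'   terms, each with `exponents`, `derivative_order` and `label`), `n_states`,
#'   `p` (number of terms) and `type = "poly"`.
#' @examples
#' lib <- feature_library(2, 5)
#' lib$p                 # 28 monomials
#' count_model_space(6)  # 63 candidate subset models for a 6-term library
#' @export
feature_library <- function(n_states, max_degree, vars = NULL) {
  if (length(n_states) != 1L || n_states < 1L || n_states != round(n_states))
    stop("n_states must be a single integer >= 1")
  if (length(max_degree) != 1L || max_degree < 0L || max_degree != round(max_degree))
    stop("max_degree must be a single integer >= 0")
  n_states <- as.integer(n_states); max_degree <- as.integer(max_degree)
  if (is.null(vars)) vars <- state_names(n_states)
  expo <- enumerate_monomials(n_states, max_degree)
  terms <- lapply(seq_len(nrow(expo)), function(i) {
    e <- as.integer(expo[i, ])
    list(exponents = e, derivative_order = 0L, label = poly_label(e, vars))
  })
  new_feature_library(terms, n_states, "poly", vars)
}

#' Build a library of polynomial-times-spatial-derivative terms for PDE data
#'
#' Candidate terms are all products `u^a * d^b u / dx^b` with
#' `0 <= a <= max_poly_degree` and `0 <= b <= max_derivative_order`, so the
#' library has `(max_poly_degree + 1) * (max_derivative_order + 1)` terms,
#' including the constant (`a = b = 0`) and the pure polynomial terms
#' (`b = 0`). Terms are ordered by derivative order, then polynomial degree.
#'
#' @param max_poly_degree maximum power of `u` (>= 0).
#' @param max_derivative_order maximum spatial-derivative order (>= 0).
#' @return a `sindy_library` with `type = "pde"` and `n_states = 1`.
#' @examples
#' pde_library(3, 3)$p  # 16 terms: {1,u,u^2,u^3} x {1,u_x,u_xx,u_xxx}
#' @export
pde_library <- function(max_poly_degree, max_derivative_order) {
  if (length(max_poly_degree) != 1L || max_poly_degree < 0L)
    stop("max_poly_degree must be a single integer >= 0")
  if (length(max_derivative_order) != 1L || max_derivative_order < 0L)
    stop("max_derivative_order must be a single integer >= 0")
  a_max <- as.integer(max_poly_degree); b_max <- as.integer(max_derivative_order)
  terms <- list()
  for (b in 0:b_max) for (a in 0:a_max) {
    terms[[length(terms) + 1L]] <-
      list(exponents = a, derivative_order = b, label = pde_label(a, b))
  }
  new_feature_library(terms, 1L, "pde", "u")
}

#' Number of candidate models representable in a p-term library
#'
#' A candidate model is a non-empty subset of library terms, so a `p`-term
#' library spans `2^p - 1` models. Exact for `p <= 53` (the result is below
#' 2^53 and therefore exactly representable as a double).
#'
#' @param p number of library terms (>= 0).
#' @return `2^p - 1` as a numeric scalar.
#' @examples
#' count_model_space(6)   # 63
#' count_model_space(28)  # 268435455
#' @export
count_model_space <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p != round(p))
    stop("p must be a single integer >= 0")
  if (p > 53) stop("p > 53: 2^p - 1 is not exactly representable")
  2^p - 1
}

# Exponent matrix (p x n_states) of a polynomial library.
exponent_matrix <- function(lib) {
  do.call(rbind, lapply(lib$terms, function(tm) tm$exponents))
}

# Evaluate all monomials of exponent matrix E at state matrix X (m x n).
monomial_columns <- function(E, X) {
  m <- nrow(X)
  out <- matrix(1, m, nrow(E))
  for (i in seq_len(nrow(E))) {
    for (j in seq_len(ncol(E))) {
      if (E[i, j] > 0L) out[, i] <- out[, i] * X[, j]^E[i, j]
    }
  }
  out
}

# Evaluate monomials at a single state vector y (fast path for integrators).
monomial_row <- function(E, y) {
  v <- rep(1, nrow(E))
  for (j in seq_along(y)) {
    ej <- E[, j]
    pos <- ej > 0L
    if (any(pos)) v[pos] <- v[pos] * y[j]^ej[pos]
  }
  v
}

#' Spatial finite-difference derivative of snapshot fields
#'
#' Differentiates each row of `U` (one row per time snapshot, one column per
#' uniform grid point) with second-order-accurate stencils: central
#' differences in the interior and one-sided formulas of matching order at
#' the boundaries. Orders 1-3 use dedicated stencils; higher orders are
#' obtained by repeated first differences.
#'
#' @param U numeric matrix (snapshots x grid points) or vector (single field).
#' @param dx uniform grid spacing (> 0).
#' @param order derivative order (>= 1).
#' @return matrix (or vector) of the same shape as `U`.
#' @export
fd_derivative <- function(U, dx, order) {
  vec <- is.null(dim(U))
  if (vec) U <- matrix(U, nrow = 1L)
  n <- ncol(U)
  if (order == 1L) {
    if (n < 3L) stop("need at least 3 grid points")
    D <- matrix(0, nrow(U), n)
    D[, 2:(n - 1)] <- (U[, 3:n] - U[, 1:(n - 2)]) / (2 * dx)
    D[, 1] <- (-3 * U[, 1] + 4 * U[, 2] - U[, 3]) / (2 * dx)
    D[, n] <- (3 * U[, n] - 4 * U[, n - 1] + U[, n - 2]) / (2 * dx)
  } else if (order == 2L) {
    if (n < 4L) stop("need at least 4 grid points")
    D <- matrix(0, nrow(U), n)
    D[, 2:(n - 1)] <- (U[, 3:n] - 2 * U[, 2:(n - 1)] + U[, 1:(n - 2)]) / dx^2
    D[, 1] <- (2 * U[, 1] - 5 * U[, 2] + 4 * U[, 3] - U[, 4]) / dx^2
    D[, n] <- (2 * U[, n] - 5 * U[, n - 1] + 4 * U[, n - 2] - U[, n - 3]) / dx^2
  } else if (order == 3L) {
    if (n < 6L) stop("need at least 6 grid points")
    D <- matrix(0, nrow(U), n)
    D[, 3:(n - 2)] <- (U[, 5:n] - 2 * U[, 4:(n - 1)] +
                         2 * U[, 2:(n - 3)] - U[, 1:(n - 4)]) / (2 * dx^3)
    fwd <- function(i) (-2.5 * U[, i] + 9 * U[, i + 1] - 12 * U[, i + 2] +
                          7 * U[, i + 3] - 1.5 * U[, i + 4]) / dx^3
    bwd <- function(i) (2.5 * U[, i] - 9 * U[, i - 1] + 12 * U[, i - 2] -
                          7 * U[, i - 3] + 1.5 * U[, i - 4]) / dx^3
    D[, 1] <- fwd(1); D[, 2] <- fwd(2)
    D[, n - 1] <- bwd(n - 1); D[, n] <- bwd(n)
  } else if (order > 3L) {
    D <- U
    for (i in seq_len(order)) D <- fd_derivative(D, dx, 1L)
  } else stop("order must be >= 1")
  if (vec) drop(D) else D
}

check_uniform_grid <- function(grid) {
  h <- diff(grid)
  if (length(h) < 1L || any(abs(h - h[1]) > 1e-8 * abs(h[1])))
    stop("spatial_grid must be uniform when derivative terms are present")
  h[1]
}

# Stack a trajectory_set into a single measurement matrix plus row index.
stack_states <- function(ts) {
  mats <- lapply(ts$trajectories, `[[`, "states")
  idx <- do.call(rbind, lapply(seq_along(mats), function(i)
    data.frame(trajectory = i, time = ts$trajectories[[i]]$times)))
  list(states = do.call(rbind, mats), row_index = idx)
}

#' Evaluate a feature library on measured states
#'
#' Builds the design matrix whose column `j` is library term `j` evaluated at
#' every measurement row. For PDE libraries, `states` holds one snapshot per
#' row (columns = spatial grid points) and the spatial-derivative factors are
#' computed by [fd_derivative()] on the uniform `spatial_grid`; rows of the
#' design matrix are then all (snapshot, grid point) pairs in snapshot-major
#' order.
#'
#' @param lib a `sindy_library`.
#' @param states a numeric matrix of measurements (rows = time points,
#'   columns = state variables; for PDE libraries columns = grid points), or a
#'   `trajectory_set`, whose trajectories are stacked.
#' @param spatial_grid uniform spatial grid, required iff the library contains
#'   derivative terms.
#' @return numeric design matrix with `lib$p` columns, term labels as column
#'   names, and a `row_index` attribute mapping rows to (trajectory, time)
#'   pairs when available.
#' @export
evaluate_library <- function(lib, states, spatial_grid = NULL) {
  row_index <- NULL
  if (inherits(states, "trajectory_set")) {
    st <- stack_states(states)
    states <- st$states
    row_index <- st$row_index
  }
  states <- as.matrix(states)
  if (anyNA(states) || any(!is.finite(states)))
    stop("states contain NA or non-finite values")
  labels <- vapply(lib$terms, `[[`, "", "label")
  if (lib$type == "poly") {
    if (ncol(states) != lib$n_states)
      stop(sprintf("states have %d columns but library expects %d",
                   ncol(states), lib$n_states))
    E <- exponent_matrix(lib)
    vals <- monomial_columns(E, states)
  } else {
    orders <- vapply(lib$terms, `[[`, 0L, "derivative_order")
    if (any(orders > 0L) && is.null(spatial_grid))
      stop("spatial_grid is required for libraries with derivative terms")
    if (!is.null(spatial_grid)) {
      if (length(spatial_grid) != ncol(states))
        stop("spatial_grid length must match the number of state columns")
      dx <- check_uniform_grid(spatial_grid)
    }
    dmats <- list(`0` = states)
    for (b in sort(unique(orders[orders > 0L])))
      dmats[[as.character(b)]] <- fd_derivative(states, dx, b)
    m <- nrow(states) * ncol(states)
    vals <- matrix(0, m, lib$p)
    for (i in seq_along(lib$terms)) {
      tm <- lib$terms[[i]]
      col <- matrix(1, nrow(states), ncol(states))
      if (tm$exponents[1] > 0L) col <- states^tm$exponents[1]
      if (tm$derivative_order > 0L)
        col <- col * dmats[[as.character(tm$derivative_order)]]
      vals[, i] <- as.vector(t(col))  # snapshot-major stacking
    }
    row_index <- expand.grid(x = seq_len(ncol(states)),
                             snapshot = seq_len(nrow(states)))[, 2:1]
  }
  colnames(vals) <- labels
  attr(vals, "row_index") <- row_index
  vals
}

#' @export
print.sindy_library <- function(x, ...) {
  cat(sprintf("Feature library (%s): %d terms over %d state variable(s)\n",
              x$type, x$p, x$n_states))
  cat(" ", paste(vapply(x$terms, `[[`, "", "label"), collapse = ", "), "\n")
  invisible(x)
}

term_labels <- function(lib) vapply(lib$terms, `[[`, "", "label")
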