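test_that("zero threshold reduces STLSQ to ordinary least squares", {
  rr <- random_regression(p = 5)
  mod <- stlsq(rr$design, rr$target, 0)
  expect_equal(mod$k, 5)
  ols <- qr.coef(qr(rr$design), rr$target)
  expect_equal(unname(mod$coefficients[, 1]), unname(ols[, 1]), tolerance = 1e-12)
})

test_that("STLSQ recovers the 1-D polynomial system from noiseless data", {
  fx <- poly1d_noiseless()
  mod <- stlsq(fx$design, fx$target, 0.05)
  expect_equal(unname(which(mod$support[, 1])), c(2, 4, 5))  # x, x^3, x^4
  expect_equal(unname(mod$coefficients[mod$support[, 1], 1]),
               c(1, -0.2, -0.1), tolerance = 1e-6)
})

test_that("a threshold above every coefficient yields the empty model", {
  rr <- random_regression(p = 4)
  mod <- stlsq(rr$design, rr$target, 1e6)
  expect_equal(mod$k, 0)
  expect_true(all(mod$coefficients == 0))
})

test_that("STLSQ outputs coincide with the exhaustive-subset oracle", {
  for (p in c(3, 5, 8)) {
    rr <- random_regression(p = p, seed = 100 + p)
    all_models <- exhaustive_fit(rr$design, rr$target)
    keys <- vapply(all_models, function(m) paste(as.integer(m$support), collapse = ""), "")
    for (thr in c(0, 0.01, 0.05, 0.2, 1, 5)) {
      mod <- stlsq(rr$design, rr$target, thr)
      if (mod$k == 0) next  # empty model is not a non-empty subset
      pos <- match(paste(as.integer(mod$support), collapse = ""), keys)
      expect_false(is.na(pos))
      expect_equal(mod$coefficients, all_models[[pos]]$coefficients,
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("converged STLSQ supports are fixed points of a threshold-refit round", {
  fx <- poly1d_noiseless()
  for (thr in c(0.01, 0.05, 0.3)) {
    mod <- stlsq(fx$design, fx$target, thr)
    refit <- sindyic:::restricted_lsq(fx$design, fx$target, mod$support)
    again <- (abs(refit$coefficients) >= thr) & (refit$coefficients != 0)
    expect_identical(again, mod$support)
  }
})

test_that("restricted fits are least-squares optimal on their support", {
  rr <- random_regression(p = 6)
  mod <- stlsq(rr$design, rr$target, 0.05)
  act <- which(mod$support[, 1])
  As <- rr$design[, act, drop = FALSE]
  resid <- rr$target[, 1] - As %*% mod$coefficients[act, 1]
  grad <- crossprod(As, resid)
  expect_lt(max(abs(grad)) / max(abs(crossprod(As, rr$target[, 1]))), 1e-8)
})

test_that("threshold sweep deduplicates supports and sorts by term count", {
  fx <- poly1d_noiseless()
  models <- sweep_thresholds(fx$design, fx$target)
  ks <- vapply(models, `[[`, 0L, "k")
  expect_false(is.unsorted(ks))
  keys <- vapply(models, function(m) paste(as.integer(m$support), collapse = ""), "")
  expect_equal(anyDuplicated(keys), 0L)
  # true support is among the candidates
  truth_key <- paste(as.integer(fx$spec$truth$support), collapse = "")
  expect_true(truth_key %in% keys)
  # producing threshold is non-increasing in k on this example
  lam <- vapply(models, `[[`, 0, "lambda_used")
  expect_false(is.unsorted(rev(lam[order(ks)])))
  # duplicated grid values yield no duplicate supports; one value -> one model
  dup <- sweep_thresholds(fx$design, fx$target, grid = c(0.05, 0.05))
  expect_equal(length(dup), 1L)
})

test_that("sweep grid must be non-empty, non-negative and ascending", {
  fx <- poly1d_noiseless()
  expect_error(sweep_thresholds(fx$design, fx$target, grid = numeric(0)))
  expect_error(sweep_thresholds(fx$design, fx$target, grid = c(-1, 1)))
  expect_error(sweep_thresholds(fx$design, fx$target, grid = c(1, 0.5)))
})

test_that("exhaustive fitting enumerates every non-empty subset", {
  rr <- random_regression(p = 2)
  models <- exhaustive_fit(rr$design, rr$target)
  expect_equal(length(models), 3L)
  supports <- lapply(models, function(m) unname(which(m$support[, 1])))
  expect_equal(supports, list(1L, 2L, c(1L, 2L)))  # bitmask order
  expect_error(exhaustive_fit(matrix(rnorm(30), 10, 3), rr$target[1:10, , drop = FALSE],
                              max_p = 2),
               "7")
})

test_that("STLSQ coefficients equal the exhaustive fit of the same support", {
  fx <- poly1d_noiseless()
  all_models <- exhaustive_fit(fx$design, fx$target)
  keys <- vapply(all_models, function(m) paste(as.integer(m$support), collapse = ""), "")
  swept <- sweep_thresholds(fx$design, fx$target)
  for (mod in swept) {
    if (mod$k == 0) next
    pos <- match(paste(as.integer(mod$support), collapse = ""), keys)
    expect_false(is.na(pos))
    expect_identical(mod$coefficients, all_models[[pos]]$coefficients)
  }
})

test_that("STRidge with zero penalty reduces to STLSQ", {
  rr <- random_regression(p = 6)
  for (tol in c(0.02, 0.1, 0.5)) {
    a <- stridge(rr$design, rr$target, ridge_penalty = 0, tol = tol)
    b <- stlsq(rr$design, rr$target, tol)
    expect_identical(a$support, b$support)
    expect_equal(a$coefficients, b$coefficients, tolerance = 1e-10)
  }
})

test_that("STRidge recovers Burgers' equation from noiseless fields", {
  fx <- burgers_noiseless()
  mod <- stridge(fx$design, fx$target, ridge_penalty = 1e-5, tol = 0.05,
                 iterations = 50)
  labels <- rownames(mod$coefficients)
  act <- labels[mod$support[, 1]]
  expect_setequal(act, c("u*u_x", "u_xx"))
  expect_equal(unname(mod$coefficients[labels == "u*u_x", 1]), -1,
               tolerance = 1e-6)
  expect_equal(unname(mod$coefficients[labels == "u_xx", 1]), 0.1,
               tolerance = 1e-6)
  # a tolerance sweep contains the 2-term support
  models <- sweep_thresholds(fx$design, fx$target, method = "stridge",
                             grid = sindyic:::stridge_tol_grid(0.1))
  expect_true(2 %in% vapply(models, `[[`, 0L, "k"))
})

test_that("rank-deficient restricted systems fall back to minimum-norm fits", {
  set.seed(7)
  A <- matrix(rnorm(20), 10, 2)
  A <- cbind(A, A[, 1] + A[, 2])  # exactly collinear third column
  colnames(A) <- c("a", "b", "c")
  y <- matrix(A[, 1] - A[, 2] + rnorm(10, sd = 0.01), ncol = 1)
  mod <- stlsq(A, y, 0)
  expect_true(mod$rank_deficient)
  expect_true(all(is.finite(mod$coefficients)))
})
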