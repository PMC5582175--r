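mk_traj <- function(states, times = seq_len(nrow(states)) - 1, diverged = FALSE) {
  list(x0 = states[1, ], times = times, states = states, diverged = diverged)
}

test_that("trajectory error implements the average-absolute-deviation contract", {
  set.seed(3)
  st <- matrix(rnorm(200), 100, 2)
  a <- mk_traj(st)
  expect_equal(trajectory_error(a, a), 0)
  b <- mk_traj(st + 0.25)
  expect_equal(trajectory_error(a, b), 0.25)
  expect_equal(trajectory_error(a, b, convention = "sum"), 0.25 * 200)
  expect_equal(trajectory_error(a, b, squared = TRUE), 0.25^2)
  expect_equal(trajectory_error(mk_traj(st, diverged = TRUE), b), Inf)
  expect_error(trajectory_error(a, mk_traj(st[1:50, ])), "time grids")
})

test_that("the mean absolute error of pure Gaussian noise approaches sd*sqrt(2/pi)", {
  set.seed(11)
  eps <- 1e-3
  st <- matrix(0, 10000, 1)
  noisy <- mk_traj(st + rnorm(10000, sd = eps))
  expect_equal(trajectory_error(mk_traj(st), noisy), eps * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("AIC uses the residual-sum surrogate with trajectories as observations", {
  expect_equal(aic_from_errors(rep(1, 10), k = 3), 6)
  expect_equal(aic_from_errors(rep(exp(1), 4), k = 0), 4)
  # common rescaling adds m log(c) to every model identically
  e <- c(0.1, 0.2, 0.4)
  for (k in 0:3)
    expect_equal(aic_from_errors(10 * e, k) - aic_from_errors(e, k),
                 3 * log(10))
  expect_equal(aic_from_errors(c(1, Inf), 2), Inf)
  expect_equal(aic_from_errors(rep(0, 5), 1), -Inf)
  expect_error(aic_from_errors(numeric(0), 1))
})

test_that("the finite-sample AIC correction matches its closed form", {
  expect_equal(aicc(10, k = 7, m = 100), 10 + 144 / 91)
  expect_warning(out <- aicc(10, k = 8, m = 10), "undefined")
  expect_equal(out, Inf)
  # correction decreases monotonically to zero in m
  gaps <- vapply(c(20, 50, 100, 1000, 1e5), function(m) aicc(0, 5, m), 0)
  expect_false(is.unsorted(rev(gaps)))
  expect_lt(gaps[5], 1e-3)
})

test_that("BIC applies the standard log-m complexity penalty", {
  e <- rep(1, 50)
  for (k in c(1, 4))
    expect_equal(bic_from_errors(e, k) - aic_from_errors(e, k),
                 k * (log(50) - 2))
  expect_gt(bic_from_errors(e, 1), aic_from_errors(e, 1))  # m > e^2
})

mk_scores <- function(aicc, k = seq_along(aicc), unstable = FALSE) {
  data.frame(model_id = seq_along(aicc), origin = "stlsq", lambda_used = 0,
             k = k, terms = letters[seq_along(aicc)], aic = aicc, aicc = aicc,
             bic = aicc, unstable = unstable, n_diverged = 0,
             mean_error = 1, m_obs = 100)
}

test_that("relative AICc classification follows the support thresholds", {
  sc <- rank_and_classify(mk_scores(100 + c(0, 1.9, 5, 12, 3)))
  expect_equal(sc$delta[order(sc$model_id)], c(0, 1.9, 5, 12, 3))
  expect_equal(sc$category[order(sc$model_id)],
               c("strong", "strong", "weak", "none", "borderline"))
  expect_false(is.unsorted(sc$delta))
  # exactly the argmin models sit at delta 0
  expect_equal(sum(sc$delta == 0), 1L)
})

test_that("unstable models never outrank finite-error models", {
  sc <- mk_scores(c(10, Inf, 12), unstable = c(FALSE, TRUE, FALSE))
  ranked <- rank_and_classify(sc)
  expect_equal(ranked$category[ranked$model_id == 2], "unstable")
  expect_equal(ranked$model_id[3], 2L)
})

test_that("scores computed at different m cannot be compared", {
  sc <- mk_scores(c(1, 2))
  sc$m_obs <- c(100, 50)
  expect_error(rank_and_classify(sc), "observations")
})

test_that("deltas and categories are invariant under common error rescaling", {
  set.seed(21)
  errs <- matrix(rexp(160, rate = 10), 8, 20)
  k <- c(1:7, 9)
  score_tab <- function(e) {
    aics <- vapply(seq_len(nrow(e)), function(i) aic_from_errors(e[i, ], k[i]), 0)
    acs <- vapply(seq_len(nrow(e)), function(i) aicc(aics[i], k[i], ncol(e)), 0)
    tab <- mk_scores(acs, k = k)
    tab$m_obs <- ncol(e)
    rank_and_classify(tab)
  }
  base <- score_tab(errs)
  for (c0 in c(10, 1 / 7, 1e3)) {
    scaled <- score_tab(c0 * errs)
    expect_equal(scaled$delta, base$delta, tolerance = 1e-10)
    expect_identical(scaled$category, base$category)
    expect_identical(scaled$model_id, base$model_id)
  }
})

test_that("equal-error models rank by parsimony", {
  sc <- mk_scores(c(10 + 2 * 3, 10 + 2 * 5), k = c(3, 5))  # same error term
  ranked <- rank_and_classify(sc)
  expect_equal(ranked$k[1], 3)
})
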