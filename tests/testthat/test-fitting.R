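test_that("Hooke-Jeeves solves the 1-D bowl", {
  r <- hooke_jeeves(function(x) (x - 0.3)^2, 0.9, lower = 0, upper = 1)
  expect_true(r$converged)
  expect_equal(r$x, 0.3, tolerance = 1e-5)
})

test_that("Hooke-Jeeves solves the Rosenbrock valley within bounds", {
  ros <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  seen_outside <- FALSE
  obj <- function(x) {
    if (any(x < 0 | x > 2)) seen_outside <<- TRUE
    ros(x)
  }
  r <- hooke_jeeves(obj, c(0.2, 0.2), lower = 0, upper = 2, max_evals = 5e4)
  expect_lt(r$f, 1e-8)
  expect_equal(r$x, c(1, 1), tolerance = 1e-3)
  expect_false(seen_outside)
  # monotone best-so-far trace
  expect_true(all(diff(r$trace) <= 0))
})

test_that("fit cost is zero at the generating truth and matches a hand value", {
  m <- build_default_model()
  truth <- m$parameters[free_parameters(m)]
  ds <- generate_timecourse_data(m, noise_model(cv = 0), seed = 5)
  expect_lt(fit_cost(truth, ds, m), 1e-14)
  # shift every IkB observation by +0.1: cost = w1 * 6 * 0.1^2 exactly
  shifted <- ds
  shifted$ikb_values <- ds$ikb_values + 0.1
  w <- cost_weights(shifted)
  expect_equal(fit_cost(truth, shifted, m, weights = w),
               unname(w[1]) * length(ds$ikb_times) * 0.01,
               tolerance = 1e-10)
})

test_that("cost weights put both observables on the same relative scale", {
  ds <- timecourse_dataset(c(0, 5), c(2, 4), c(0, 10), c(0.01, 0.02))
  w <- cost_weights(ds)
  expect_equal(unname(w[1]), 1 / (2^2 + 4^2))
  expect_equal(unname(w[2]), 1 / (0.01^2 + 0.02^2))
})

test_that("integration failure maps to the penalty", {
  m <- build_default_model()
  ds <- generate_timecourse_data(m, noise_model(cv = 0), seed = 5)
  bad <- m$parameters[free_parameters(m)]
  bad[] <- NA_real_
  expect_equal(fit_cost(bad, ds, m), 1e6)
})

test_that("multistart fit is deterministic under a fixed seed", {
  m <- build_default_model()
  ds <- generate_timecourse_data(m, noise_model(cv = 0), seed = 5)
  f1 <- multistart_fit(ds, m, n_starts = 1, seed = 11, max_evals = 150)
  f2 <- multistart_fit(ds, m, n_starts = 1, seed = 11, max_evals = 150)
  expect_identical(f1$per_run, f2$per_run)
  expect_equal(f1$best_params, f2$best_params)
  expect_true(all(f1$best_params >= 0 & f1$best_params <= 1))
})

test_that("with_free_parameters installs and rejects as documented", {
  m <- build_default_model()
  m2 <- with_free_parameters(m, c(t1 = 0.2, g7 = 0.11))
  expect_equal(unname(m2$parameters[["t1"]]), 0.2)
  expect_equal(unname(m2$parameters[["g7"]]), 0.11)
  expect_error(with_free_parameters(m, c(a1 = 0.5)))
})

test_that("dataset container validates its inputs", {
  expect_error(timecourse_dataset(c(0, 5), c(1, -1), 0, 1), "non-negative")
  expect_error(timecourse_dataset(c(0, 5), 1, 0, 1))
})
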