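test_that("integration reproduces analytic exponential decay", {
  m <- toy_decay_model(k = 0.3, x0 = 2)
  tt <- seq(0, 10, by = 0.5)
  tc <- integrate_model(m, tt)
  expect_s3_class(tc, "timecourse")
  expect_equal(species_trace(tc, "X"), 2 * exp(-0.3 * tt), tolerance = 1e-6)
})

test_that("reversible binding relaxes to its mass-action equilibrium", {
  m <- toy_binding_model(ka = 2, kd = 1, a0 = 1, b0 = 0.6)
  ss <- steady_state(m, tol = 1e-9)
  expect_true(ss$converged)
  s <- ss$state
  expect_equal(2 * s[["A"]] * s[["B"]], 1 * s[["C"]], tolerance = 1e-6)
  # conservation of the A and B moieties
  expect_equal(s[["A"]] + s[["C"]], 1, tolerance = 1e-6)
  expect_equal(s[["B"]] + s[["C"]], 0.6, tolerance = 1e-6)
})

test_that("trajectories are robust to solver tolerance", {
  m <- build_default_model()
  tt <- c(0, 30, 60, 120)
  tight <- integrate_model(m, tt)
  loose <- integrate_model(m, tt, rtol = 1e-6, atol = 1e-8)
  expect_equal(species_trace(loose, "NFkBn"), species_trace(tight, "NFkBn"),
               tolerance = 1e-4)
})

test_that("conserved moieties stay constant along the pathway trajectory", {
  m <- build_default_model()
  tc <- integrate_model(m, seq(0, 300, by = 10))
  nfkb_tot <- rowSums(tc$states[, NFKB_MOIETY])
  ikk_tot <- rowSums(tc$states[, IKK_MOIETY])
  expect_equal(nfkb_tot, rep(0.91, length(tc$times)), tolerance = 1e-7)
  expect_equal(ikk_tot, rep(0.2, length(tc$times)), tolerance = 1e-7)
})

test_that("baseline steady state converges to a positive nuclear output", {
  m <- build_default_model()
  ss <- steady_state(m)
  expect_true(ss$converged)
  expect_false(ss$oscillatory)
  expect_lt(ss$residual, 1e-6)
  expect_gt(ss$state[["NFkBn"]], 0)
})

test_that("integration input validation", {
  m <- toy_decay_model()
  expect_error(integrate_model(m, c(2, 1)), "strictly increasing")
  expect_error(integrate_model(m, numeric(0)), "non-empty")
  expect_error(integrate_model(m, 0:3, init = c(X = -1)), "non-negative")
})
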