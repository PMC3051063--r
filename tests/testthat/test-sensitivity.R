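test_that("linear surrogate gives S = 1 (and -1 for the decay rate)", {
  m <- toy_birth_death_model(k = 0.04, d = 0.5)
  s_k <- sensitivity_coefficient(m, "k", "kinetic")
  s_d <- sensitivity_coefficient(m, "d", "kinetic")
  expect_equal(s_k$S_mean, 1, tolerance = 1e-3)
  expect_equal(s_d$S_mean, -1, tolerance = 1e-2)
  expect_false(s_k$flagged)
})

test_that("a dead-end species has zero sensitivity", {
  m <- toy_birth_death_model(dead0 = 0.3)
  s <- sensitivity_coefficient(m, "Dead", "initial")
  expect_equal(s$S_mean, 0, tolerance = 1e-9)
  expect_equal(s$output_change_percent, 0, tolerance = 1e-6)
})

test_that("finite differences are consistent across perturbation sizes", {
  m <- build_default_model()
  baseline <- nuclear_nfkb_output(m)
  s1 <- sensitivity_coefficient(m, "t1", "kinetic", delta_fraction = 0.01,
                                baseline = baseline)
  s2 <- sensitivity_coefficient(m, "t1", "kinetic", delta_fraction = 0.005,
                                baseline = baseline)
  expect_lt(abs(s1$S_mean - s2$S_mean) / abs(s2$S_mean), 0.05)
})

test_that("sensitivity scan table is complete, sorted and writable", {
  m <- toy_birth_death_model()
  tab <- sensitivity_scan(m)
  # 2 kinetic parameters + 1 nonzero initial
  expect_equal(nrow(tab), 3)
  expect_true(all(c("target", "kind", "S_mean", "flagged") %in% names(tab)))
  expect_true(!is.unsorted(rev(abs(tab$S_mean))))
  expect_equal(attr(tab, "baseline_output"), 0.04 / 0.5, tolerance = 1e-4)
  p <- tempfile(fileext = ".csv")
  write_sensitivity(tab, p)
  back <- read.csv(p)
  expect_equal(nrow(back), 3)
  unlink(p)
})

test_that("unknown targets are rejected", {
  m <- build_default_model()
  expect_error(sensitivity_coefficient(m, "zz", "kinetic"),
               "unknown parameter")
  expect_error(sensitivity_coefficient(m, "zz", "initial"),
               "unknown species")
})
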