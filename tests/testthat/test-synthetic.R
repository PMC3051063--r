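test_that("noise model validates its arguments", {
  expect_error(noise_model(cv = -0.1))
  expect_error(noise_model(replicates = 0))
  expect_equal(noise_model()$kind, "multiplicative_lognormal")
})

test_that("zero-noise data equal the model's own trajectory", {
  m <- build_default_model()
  ds <- generate_timecourse_data(m, noise_model(cv = 0), seed = 2)
  grid <- sort(unique(c(ds$ikb_times, ds$nfkb_times)))
  tc <- integrate_model(m, grid)
  expect_equal(ds$ikb_times, c(0, 5, 10, 15, 20, 30))
  expect_equal(ds$nfkb_times, c(0, 10, 20, 30, 60, 120))
  expect_equal(ds$ikb_values,
               unname((tc$states[, "IkB"] +
                       tc$states[, "IkB_NFkB"])[match(ds$ikb_times, grid)]),
               tolerance = 1e-12)
  expect_equal(ds$nfkb_values,
               unname(tc$states[match(ds$nfkb_times, grid), "NFkBn"]),
               tolerance = 1e-12)
})

test_that("multiplicative noise is non-negative, unbiased and seeded", {
  m <- build_default_model()
  ds1 <- generate_timecourse_data(m, noise_model(cv = 0.1, replicates = 3),
                                  seed = 9)
  ds2 <- generate_timecourse_data(m, noise_model(cv = 0.1, replicates = 3),
                                  seed = 9)
  ds3 <- generate_timecourse_data(m, noise_model(cv = 0.1, replicates = 3),
                                  seed = 10)
  expect_identical(ds1$replicates, ds2$replicates)
  expect_false(identical(ds1$replicates, ds3$replicates))
  expect_true(all(ds1$replicates$value >= 0))
  expect_match(ds1$provenance, "seed=9")
  # the log-normal factors have unit mean: many replicates average to truth
  big <- generate_timecourse_data(m, noise_model(cv = 0.1, replicates = 400),
                                  seed = 4)
  truth <- generate_timecourse_data(m, noise_model(cv = 0), seed = 4)
  expect_equal(big$ikb_values, truth$ikb_values, tolerance = 0.02)
})

test_that("the replicate table matches the stored means", {
  m <- build_default_model()
  ds <- generate_timecourse_data(m, noise_model(cv = 0.2, replicates = 5),
                                 seed = 6)
  reps <- ds$replicates
  ikb5 <- reps$value[reps$observable == "IkB_cyt" & reps$time_min == 5]
  expect_equal(mean(ikb5), ds$ikb_values[ds$ikb_times == 5],
               tolerance = 1e-12)
  expect_equal(length(ikb5), 5)
})

test_that("true_params overrides reach the generator", {
  m <- build_default_model()
  ds_alt <- generate_timecourse_data(m, noise_model(cv = 0), seed = 2,
                                     true_params = c(t1 = 0.05))
  ds_def <- generate_timecourse_data(m, noise_model(cv = 0), seed = 2)
  expect_false(isTRUE(all.equal(ds_alt$nfkb_values, ds_def$nfkb_values)))
})
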