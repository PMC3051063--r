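test_that("Bliss CI is exactly 1 on Bliss-independent surrogates", {
  for (E1 in c(0.1, 0.35, 0.8)) {
    for (E2 in c(0.05, 0.5, 0.95)) {
      E12 <- E1 + E2 - E1 * E2
      expect_equal(bliss_ci(E1, E2, E12), 1, tolerance = 1e-12)
    }
  }
  expect_true(is.na(bliss_ci(0.2, 0.3, 0)))
  expect_error(bliss_ci(1.2, 0.1, 0.5), "\\[0, 1\\]")
})

test_that("Bliss classification boundaries behave as printed", {
  expect_equal(classify_bliss(c(0.9899, 0.99, 1, 1.01, 1.0101, NA)),
               c("synergy", "additive", "additive", "additive",
                 "antagonism", "undefined"))
  expect_error(classify_bliss(1, threshold_down = 1.1, threshold_up = 1))
})

test_that("ic_x inverts a hyperbolic curve", {
  d <- seq(0, 5, by = 0.005)
  curve <- data.frame(dose = d, inhibition = d / (1 + d))
  expect_equal(ic_x(curve, 0.5), 1, tolerance = 1e-3)
  expect_equal(ic_x(curve, 0.25), 1 / 3, tolerance = 1e-3)
  expect_error(ic_x(curve, 0.99), "not achievable")
  expect_error(ic_x(curve, 0))
})

test_that("curve shape classifier separates Hill n = 1 from n = 4", {
  d <- seq(0, 5, by = 0.25)
  expect_equal(nfkbdrug:::curve_shape(d, d / (1 + d)), "hyperbolic")
  expect_equal(nfkbdrug:::curve_shape(d, d^4 / (1 + d^4)), "sigmoidal")
  expect_equal(nfkbdrug:::curve_shape(d, rep(0, length(d))), "flat")
})

test_that("dose-response curve on the model is monotone with zero at zero", {
  m <- build_default_model()
  cr <- dose_response_curve(m, "D4", c(0, 0.25, 0.5, 0.75, 1))
  expect_s3_class(cr, "dose_response_curve")
  expect_equal(cr$inhibition[1], 0)
  expect_true(attr(cr, "monotone"))
  expect_gt(attr(cr, "control_output"), 0)
})

test_that("a small combination grid is internally consistent", {
  m <- build_default_model()
  map <- combination_grid(m, "D2", "D4", rangeA = 4, rangeB = 1,
                          n_levels = 3)
  expect_s3_class(map, "synergy_map")
  expect_equal(dim(map$E12), c(3, 3))
  expect_equal(map$dosesA, (1:3) * 4 / 3)
  # CI recomputed from the stored effects matches the stored CI
  expected_ci <- outer(map$E1, map$E2, function(a, b) a + b - a * b) /
    map$E12
  expect_equal(map$ci, expected_ci, tolerance = 1e-12)
  expect_equal(as.vector(map$class),
               classify_bliss(as.vector(map$ci)))
  counts <- synergy_class_counts(map)
  expect_equal(sum(counts), 9)
  # diagonal cell agrees with a direct simulation
  direct <- inhibition_rate(m, c(D2 = map$dosesA[2], D4 = map$dosesB[2]),
                            control_output = map$control_output)
  expect_equal(map$E12[2, 2], direct, tolerance = 1e-9)
})

test_that("synergy map and isobologram writers produce the artifacts", {
  m <- build_default_model()
  map <- combination_grid(m, "D2", "D4", 4, 1, n_levels = 2)
  dir <- tempfile("synmap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  files <- write_synergy_map(map, dir)
  expect_true(all(file.exists(files)))
  meta <- jsonlite::read_json(files[grepl("meta", files)])
  expect_equal(meta$drugA, "D2")
  expect_equal(sum(unlist(meta$class_counts)), 4)
})

test_that("Loewe isobole endpoints anchor at CI = 1", {
  m <- build_default_model()
  cA <- dose_response_curve(m, "D2", seq(0, 4, length.out = 9))
  cB <- dose_response_curve(m, "D4", seq(0, 1, length.out = 9))
  iso <- loewe_isobole(m, "D2", "D4", 0.25, cA, cB, resolution = 3)
  expect_s3_class(iso, "isobologram")
  expect_equal(iso$loewe_ci[1], 1)
  expect_equal(iso$loewe_ci[nrow(iso)], 1)
  expect_equal(iso$d2[1], 0)
  expect_equal(iso$d1[nrow(iso)], 0)
  expect_equal(attr(iso, "icx"), c(ic_x(cA, 0.25), ic_x(cB, 0.25)))
  expect_true(all(iso$loewe_ci > 0))
})
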