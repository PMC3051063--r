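test_that("Hill inhibition closed forms", {
  expect_equal(hill_inhibition(0), 0)
  expect_equal(hill_inhibition(1e-9^(1 / 4)), 0.5)
  expect_equal(hill_inhibition(2, n = 3, K = 8), 0.5)
  d <- seq(0, 0.02, by = 0.001)
  expect_true(all(diff(hill_inhibition(d)) > 0))
  expect_true(all(hill_inhibition(d) >= 0 & hill_inhibition(d) < 1))
  expect_error(hill_inhibition(-1), "non-negative")
  expect_error(hill_inhibition(1, n = 0), "n > 0")
})

test_that("default drugs have the documented mechanisms and targets", {
  drugs <- default_drugs()
  expect_named(drugs, c("D1", "D2", "D3", "D4"))
  expect_equal(drugs$D1$target, "TNFa")
  expect_equal(drugs$D2$target, "IKKp")
  expect_equal(drugs$D4$target, "NFkB")
  expect_equal(drugs$D3$mechanism, "proteasome_inhibition")
  expect_equal(sort(drugs$D3$target), sort(PROTEASOME_PARAMS))
  expect_equal(drugs$D3$hill_n, 4)
  expect_equal(drugs$D3$hill_K, 1e-9)
})

test_that("binding drug extends the model by two species and two reactions", {
  m <- build_default_model()
  spec <- default_drugs()$D4
  spec$dose <- 0.5
  m2 <- apply_drug(m, spec)
  expect_equal(nrow(m2$species), 28)
  expect_equal(nrow(m2$reactions), 41)
  expect_equal(length(m2$parameters), 41)
  expect_equal(unname(m2$initial[["D4"]]), 0.5)
  expect_equal(unname(m2$initial[["D4_NFkB"]]), 0)
  # drug kinetics are not estimated
  expect_equal(length(free_parameters(m2)), 21)
})

test_that("the drug moiety is conserved along the trajectory", {
  m <- build_default_model()
  spec <- default_drugs()$D4
  spec$dose <- 0.5
  m2 <- apply_drug(m, spec)
  tc <- integrate_model(m2, seq(0, 200, by = 5))
  total <- tc$states[, "D4"] + tc$states[, "D4_NFkB"]
  expect_equal(total, rep(0.5, length(tc$times)), tolerance = 1e-7)
})

test_that("zero dose is neutral for both mechanisms", {
  m <- build_default_model()
  y0 <- nuclear_nfkb_output(m)
  expect_equal(nuclear_nfkb_output(m, c(D2 = 0)), y0, tolerance = 1e-7)
  d3 <- default_drugs()$D3
  expect_identical(apply_drug(m, d3)$parameters, m$parameters)
})

test_that("proteasome inhibitor scales exactly its target constants", {
  m <- build_default_model()
  spec <- default_drugs()$D3
  spec$dose <- 0.0055
  m2 <- apply_drug(m, spec)
  f <- hill_inhibition(0.0055, 4, 1e-9)
  expect_equal(m2$parameters[PROTEASOME_PARAMS],
               m$parameters[PROTEASOME_PARAMS] * (1 - f))
  untouched <- setdiff(names(m$parameters), PROTEASOME_PARAMS)
  expect_identical(m2$parameters[untouched], m$parameters[untouched])
})

test_that("drug specification is validated", {
  expect_error(drug_spec("X", "competitive_binding", "TNFa"),
               "binding_rate")
  expect_error(drug_spec("X", "proteasome_inhibition", "g4",
                         hill_n = 0, hill_K = 1), "hill_n")
  expect_error(drug_spec("X", "competitive_binding", "TNFa",
                         binding_rate = 1, dissociation_rate = 1,
                         dose = -1), "non-negative")
  m <- build_default_model()
  bad <- drug_spec("X", "competitive_binding", "NoSuch",
                   binding_rate = 1, dissociation_rate = 1)
  expect_error(apply_drug(m, bad), "not in model")
})
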