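test_that("canonical inventories have the documented sizes", {
  sp <- nfkb_species()
  rx <- nfkb_reactions()
  expect_equal(nrow(sp), 26)
  expect_equal(nrow(rx), 39)
  expect_equal(anyDuplicated(sp$id), 0)
  expect_equal(anyDuplicated(rx$id), 0)
  expect_equal(length(unique(rx$rate_constant)), 39)
  expect_equal(length(FIXED_PARAMS), 18)
  expect_true(all(FIXED_PARAMS %in% rx$rate_constant))
})

test_that("stoichiometry matrix encodes signed net counts", {
  rx <- data.frame(id = c("bind", "make"),
                   reactants = c("A+B", ""), products = c("C", "2*A"),
                   rate_constant = c("k1", "k2"),
                   kind = c("association", "synthesis"),
                   subsystem = "cyto_core", stringsAsFactors = FALSE)
  S <- stoichiometry_matrix(c("A", "B", "C"), rx)
  expect_equal(S[, "bind"], c(A = -1L, B = -1L, C = 1L))
  expect_equal(S[, "make"], c(A = 2L, B = 0L, C = 0L))
})

test_that("mass-action flux follows the law of mass action", {
  rx <- data.frame(id = "r", reactants = "A+B", products = "C",
                   rate_constant = "k", kind = "association",
                   subsystem = "cyto_core", stringsAsFactors = FALSE)
  expect_equal(mass_action_flux(rx[1, ], c(A = 0.5, B = 0.2, C = 9),
                                c(k = 3)), 3 * 0.5 * 0.2)
  syn <- data.frame(id = "s", reactants = "", products = "A",
                    rate_constant = "k", kind = "synthesis",
                    subsystem = "cyto_core", stringsAsFactors = FALSE)
  expect_equal(mass_action_flux(syn[1, ], c(A = 7), c(k = 0.11)), 0.11)
})

test_that("default model builds and validates", {
  m <- build_default_model()
  v <- validate_model(m)
  expect_true(v$ok)
  expect_equal(unname(v$counts["species"]), 26)
  expect_equal(unname(v$counts["parameters"]), 39)
  expect_equal(unname(v$counts["free"]), 21)
  expect_equal(unname(v$counts["nonzero_init"]), 11)
  expect_true(v$checks[["nfkb_moiety_conserved"]])
  expect_true(v$checks[["ikk_moiety_conserved"]])
  expect_equal(sort(free_parameters(m)),
               sort(setdiff(names(m$parameters), FIXED_PARAMS)))
})

test_that("prior and fitted parameter sets differ, TNFa dose is settable", {
  mf <- build_default_model("fitted")
  mp <- build_default_model("prior", tnfa_dose = 0.7)
  expect_false(identical(mf$parameters, mp$parameters))
  expect_equal(unname(mp$initial[["TNFa"]]), 0.7)
  expect_equal(unname(mf$initial[["TNFa"]]), 0.2)
})

test_that("model constructor rejects broken inputs", {
  sp <- nfkb_species()
  rx <- nfkb_reactions()
  p <- build_default_model()$parameters
  init <- default_initial_concentrations()
  expect_error(pathway_model(sp[-1, ], rx, p, init["TNFR1"]),
               "unknown species")
  expect_error(pathway_model(sp, rx, p[-1], init), "missing rate constants")
  bad <- init
  bad["TNFa"] <- -1
  expect_error(pathway_model(sp, rx, p, bad), "non-negative")
})

test_that("R and compiled right-hand sides agree at several states", {
  m <- build_default_model()
  f <- assemble_odes(m)
  packed <- nfkbdrug:::pack_model(m)
  set.seed(7)
  for (i in 1:5) {
    y <- m$initial * stats::runif(length(m$initial), 0.5, 1.5)
    dx_r <- f(0, y)[[1]]
    dx_c <- .Call("massaction_eval", packed, as.double(y),
                  PACKAGE = "nfkbdrug")
    expect_equal(dx_c, dx_r, tolerance = 1e-12)
  }
})
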