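#' Specify a drug acting on the pathway
#'
#' Two mechanisms are supported. `competitive_binding`: the drug is an
#' additional dynamic species that reversibly sequesters its target species
#' into an inert complex (mass action, no clearance; its initial
#' concentration equals the dose). `proteasome_inhibition`: the drug scales
#' the proteasome-dependent IkBa degradation rate constants by
#' `1 - f(dose)` where `f` is the Hill-type occupancy [hill_inhibition()];
#' no species is added.
#'
#' @param id drug identifier (e.g. `"D1"`).
#' @param mechanism `"competitive_binding"` or `"proteasome_inhibition"`.
#' @param target target species id (binding drugs) or character vector of
#'   rate-constant symbols (proteasome drugs).
#' @param binding_rate,dissociation_rate kinetics of the sequestration
#'   reaction (1/(uM min), 1/min); binding drugs only.
#' @param hill_n,hill_K Hill coefficient (dimensionless) and constant
#'   (uM^n); proteasome drugs only.
#' @param dose dose in uM (>= 0).
#' @return A `drug_spec`.
#' @export
drug_spec <- function(id, mechanism, target, binding_rate = NULL,
                      dissociation_rate = NULL, hill_n = NULL,
                      hill_K = NULL, dose = 0) {
  mechanism <- match.arg(mechanism,
                         c("competitive_binding", "proteasome_inhibition"))
  if (dose < 0) stop("dose must be non-negative")
  if (mechanism == "competitive_binding") {
    if (is.null(binding_rate) || is.null(dissociation_rate))
      stop("binding drugs need binding_rate and dissociation_rate")
    stopifnot(length(target) == 1)
  } else {
    if (is.null(hill_n) || is.null(hill_K) || hill_n <= 0 || hill_K <= 0)
      stop("proteasome drugs need hill_n > 0 and hill_K > 0")
    if (length(target) < 1) stop("proteasome drugs need target parameters")
  }
  structure(list(id = id, mechanism = mechanism, target = target,
                 binding_rate = binding_rate,
                 dissociation_rate = dissociation_rate,
                 hill_n = hill_n, hill_K = hill_K, dose = dose),
            class = "drug_spec")
}

#' The four default inhibitors
#'
#' D1 (infliximab-like) sequesters TNFa with the kinetics of the
#' TNFa-receptor reaction (a1/d1); D2 (arsenic-trioxide-like) sequesters
#' active IKK with the kinetics of the IKKp-IkBa reaction (a7/d7); D3
#' (bortezomib-like) inhibits the proteasome, scaling the four IkBa
#' degradation-route constants by a Hill factor with n = 4 and
#' K = 1e-9 uM^4 (half-inhibition near 0.0055 uM); D4 (A238L-like)
#' sequesters cytoplasmic NFkB with the kinetics of the NFkB-IkBa
#' reaction (a6/d6).
#'
#' @param params rate-constant set the binding templates are drawn from;
#'   defaults to the shipped calibrated set.
#' @return Named list of `drug_spec` objects (`D1`..`D4`).
#' @export
default_drugs <- function(params = NULL) {
  if (is.null(params))
    params <- read_parameters(system.file("extdata", "params_fitted.csv",
                                          package = "nfkbdrug",
                                          mustWork = TRUE))
  list(
    D1 = drug_spec("D1", "competitive_binding", "TNFa",
                   binding_rate = params[["a1"]],
                   dissociation_rate = params[["d1"]]),
    D2 = drug_spec("D2", "competitive_binding", "IKKp",
                   binding_rate = params[["a7"]],
                   dissociation_rate = params[["d7"]]),
    D3 = drug_spec("D3", "proteasome_inhibition", PROTEASOME_PARAMS,
                   hill_n = 4, hill_K = 1e-9),
    D4 = drug_spec("D4", "competitive_binding", "NFkB",
                   binding_rate = params[["a6"]],
                   dissociation_rate = params[["d6"]])
  )
}

#' Hill-type proteasome-inhibition occupancy
#'
#' `f(dose) = dose^n / (K + dose^n)`: the inhibited fraction of IkBa
#' degradation activity at a given proteasome-inhibitor dose. Monotone
#' increasing, `f(0) = 0`, `f -> 1` as dose grows.
#'
#' @param dose dose (uM), scalar or vector, >= 0.
#' @param n Hill coefficient (> 0).
#' @param K Hill constant (uM^n, > 0).
#' @return Inhibited fraction in `[0, 1)`.
#' @export
hill_inhibition <- function(dose, n = 4, K = 1e-9) {
  stopifnot(n > 0, K > 0)
  if (any(dose < 0)) stop("dose must be non-negative")
  dose^n / (K + dose^n)
}

#' Apply a competitive-binding drug to a model
#'
#' Adds two species (the free drug and the inert drug:target complex) and a
#' reversible sequestration reaction with the spec's kinetics. The free
#' drug's initial concentration is the dose; the complex participates in no
#' other reaction, so the drug moiety is conserved.
#'
#' @param model a `pathway_model`.
#' @param spec a `drug_spec` with mechanism `competitive_binding`.
#' @return Extended `pathway_model`.
#' @export
apply_competitive_binding_drug <- function(model, spec) {
  stopifnot(inherits(spec, "drug_spec"),
            spec$mechanism == "competitive_binding")
  if (!(spec$target %in% model$species$id))
    stop("drug target not in model: ", spec$target)
  did <- spec$id
  cplx <- paste0(did, "_", spec$target)
  comp <- model$species$compartment[model$species$id == spec$target]
  sub <- model$species$subsystem[model$species$id == spec$target]
  species <- rbind(model$species,
    data.frame(id = did, display_name = paste("drug", did),
               compartment = comp, subsystem = sub),
    data.frame(id = cplx, display_name = paste0(did, ":", spec$target),
               compartment = comp, subsystem = sub))
  ka <- paste0("a_", did)
  kd <- paste0("d_", did)
  reactions <- rbind(model$reactions,
    data.frame(id = paste0("rx_", did, "_on"),
               reactants = paste0(did, "+", spec$target), products = cplx,
               rate_constant = ka, kind = "association", subsystem = sub),
    data.frame(id = paste0("rx_", did, "_off"),
               reactants = cplx, products = paste0(did, "+", spec$target),
               rate_constant = kd, kind = "dissociation", subsystem = sub))
  params <- c(model$parameters,
              setNames(c(spec$binding_rate, spec$dissociation_rate),
                       c(ka, kd)))
  init <- model$initial
  init[did] <- spec$dose
  init[cplx] <- 0
  pathway_model(species, reactions, params, init,
                fixed = c(model$fixed, ka, kd))
}

#' Apply a proteasome inhibitor to a model
#'
#' Scales each targeted degradation-route rate constant `p` to
#' `p * (1 - f(dose))` with `f` from [hill_inhibition()]. No species is
#' added; at dose 0 the model is unchanged.
#'
#' @param model a `pathway_model`.
#' @param spec a `drug_spec` with mechanism `proteasome_inhibition`.
#' @return `pathway_model` with scaled parameters.
#' @export
apply_proteasome_inhibitor <- function(model, spec) {
  stopifnot(inherits(spec, "drug_spec"),
            spec$mechanism == "proteasome_inhibition")
  missing_k <- setdiff(spec$target, names(model$parameters))
  if (length(missing_k))
    stop("target parameters not in model: ",
         paste(missing_k, collapse = ", "))
  f <- hill_inhibition(spec$dose, spec$hill_n, spec$hill_K)
  m <- model
  m$parameters[spec$target] <- m$parameters[spec$target] * (1 - f)
  m
}

#' Apply any drug to a model
#' @param model a `pathway_model`.
#' @param spec a `drug_spec`.
#' @export
apply_drug <- function(model, spec) {
  switch(spec$mechanism,
         competitive_binding = apply_competitive_binding_drug(model, spec),
         proteasome_inhibition = apply_proteasome_inhibitor(model, spec))
}
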