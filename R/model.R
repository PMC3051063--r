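#' @importFrom stats setNames
NULL

# Closed vocabularies for the pathway data model.
COMPARTMENTS <- c("cytoplasm", "nucleus")
SUBSYSTEMS   <- c("receptor", "ikk_cascade", "cyto_core", "nuclear")
REACTION_KINDS <- c("association", "dissociation", "catalysis",
                    "synthesis", "degradation", "transport")

#' Species inventory of the canonical NFkB pathway model
#'
#' Twenty-six species across four sub-systems: the TNFa receptor module
#' (ligand, receptor, adaptor, TRAFs and their complexes), the IKK
#' phosphorylation cascade (IKKK and IKK in inactive/active forms plus the
#' kinase-substrate complexes), the cytoplasmic IKK-IkB-NFkB core (free and
#' complexed NFkB, native and phosphorylated IkB, IkB mRNA), and the nuclear
#' IkB-NFkB module.
#'
#' @return A data.frame with columns `id`, `display_name`, `compartment`,
#'   `subsystem`.
#' @export
nfkb_species <- function() {
  sp <- function(id, name, comp, sub) data.frame(
    id = id, display_name = name, compartment = comp, subsystem = sub,
    stringsAsFactors = FALSE)
  rbind(
    sp("TNFa",    "TNFa",                 "cytoplasm", "receptor"),
    sp("TNFR1",   "TNF receptor 1",       "cytoplasm", "receptor"),
    sp("TNFR1C",  "TNFa:TNFR1",           "cytoplasm", "receptor"),
    sp("TNFR1A",  "TNFR1 adaptor",        "cytoplasm", "receptor"),
    sp("TNFR1AC", "TNFR1C:TNFR1A",        "cytoplasm", "receptor"),
    sp("TRAFs",   "TRAF proteins",        "cytoplasm", "receptor"),
    sp("TRAFsC",  "TNFR1AC:TRAFs",        "cytoplasm", "receptor"),
    sp("IKKK",      "IKK kinase",             "cytoplasm", "ikk_cascade"),
    sp("TRAFsC_IKKK", "TRAFsC:IKKK",          "cytoplasm", "ikk_cascade"),
    sp("IKKKp",     "phospho-IKKK",           "cytoplasm", "ikk_cascade"),
    sp("IKK",       "IKK",                    "cytoplasm", "ikk_cascade"),
    sp("IKKKp_IKK", "IKKKp:IKK",              "cytoplasm", "ikk_cascade"),
    sp("IKKp",      "phospho-IKK",            "cytoplasm", "ikk_cascade"),
    sp("NFkB",          "NFkB (p50/p65)",       "cytoplasm", "cyto_core"),
    sp("IkB",           "IkBa",                 "cytoplasm", "cyto_core"),
    sp("IkB_NFkB",      "IkBa:NFkB",            "cytoplasm", "cyto_core"),
    sp("IKKp_IkB",      "IKKp:IkBa",            "cytoplasm", "cyto_core"),
    sp("IKKp_IkB_NFkB", "IKKp:IkBa:NFkB",       "cytoplasm", "cyto_core"),
    sp("IkBp",          "phospho-IkBa",         "cytoplasm", "cyto_core"),
    sp("IkBp_NFkB",     "phospho-IkBa:NFkB",    "cytoplasm", "cyto_core"),
    sp("IkB_mRNA",      "IkBa mRNA",            "cytoplasm", "cyto_core"),
    sp("IKKp_IkBp",     "IKKp:phospho-IkBa",    "cytoplasm", "cyto_core"),
    sp("IKKp_IkBp_NFkB","IKKp:phospho-IkBa:NFkB","cytoplasm","cyto_core"),
    sp("NFkBn",      "nuclear NFkB",        "nucleus", "nuclear"),
    sp("IkBn",       "nuclear IkBa",        "nucleus", "nuclear"),
    sp("IkBn_NFkBn", "nuclear IkBa:NFkB",   "nucleus", "nuclear")
  )
}

#' Mass-action reaction table of the canonical model
#'
#' Thirty-nine reactions, each governed by exactly one rate constant (pure
#' mass action; enzymatic steps are expanded into bind / catalyze / release
#' elementary reactions rather than Michaelis-Menten forms). Reactants and
#' products are encoded as `+`-separated species ids; a count prefix such as
#' `2*A` denotes stoichiometry greater than one; an empty string denotes the
#' null species (synthesis sources / degradation sinks).
#'
#' @return A data.frame with columns `id`, `reactants`, `products`,
#'   `rate_constant`, `kind`, `subsystem`.
#' @export
nfkb_reactions <- function() {
  rx <- function(id, re, pr, k, kind, sub) data.frame(
    id = id, reactants = re, products = pr, rate_constant = k, kind = kind,
    subsystem = sub, stringsAsFactors = FALSE)
  rbind(
    # -- TNFa receptor sub-system ------------------------------------------
    rx("r01", "TNFa+TNFR1",     "TNFR1C",        "a1", "association",  "receptor"),
    rx("r02", "TNFR1C",         "TNFa+TNFR1",    "d1", "dissociation", "receptor"),
    rx("r03", "TNFR1C+TNFR1A",  "TNFR1AC",       "a2", "association",  "receptor"),
    rx("r04", "TNFR1AC",        "TNFR1C+TNFR1A", "d2", "dissociation", "receptor"),
    rx("r05", "TNFR1AC+TRAFs",  "TRAFsC",        "a3", "association",  "receptor"),
    rx("r06", "TRAFsC",         "TNFR1AC+TRAFs", "d3", "dissociation", "receptor"),
    # -- IKK phosphorylation cascade ---------------------------------------
    rx("r07", "TRAFsC+IKKK",    "TRAFsC_IKKK",   "a4", "association",  "ikk_cascade"),
    rx("r08", "TRAFsC_IKKK",    "TRAFsC+IKKK",   "d4", "dissociation", "ikk_cascade"),
    rx("r09", "TRAFsC_IKKK",    "TRAFsC+IKKKp",  "c1", "catalysis",    "ikk_cascade"),
    rx("r10", "IKKKp+IKK",      "IKKKp_IKK",     "a5", "association",  "ikk_cascade"),
    rx("r11", "IKKKp_IKK",      "IKKKp+IKK",     "d5", "dissociation", "ikk_cascade"),
    rx("r12", "IKKKp_IKK",      "IKKKp+IKKp",    "c2", "catalysis",    "ikk_cascade"),
    rx("r13", "IKKKp",          "IKKK",          "c3", "catalysis",    "ikk_cascade"),
    rx("r14", "IKKp",           "IKK",           "c4", "catalysis",    "ikk_cascade"),
    rx("r15", "IKK",            "IKKp",          "b1", "catalysis",    "ikk_cascade"),
    rx("r16", "IKKK",           "IKKKp",         "b2", "catalysis",    "ikk_cascade"),
    rx("r17", "IKKKp_IKK",      "IKKK+IKK",      "c7", "catalysis",    "ikk_cascade"),
    rx("r18", "IKKp_IkB",       "IKK+IkB",       "c8", "catalysis",    "ikk_cascade"),
    # -- cytoplasmic IKK-IkB-NFkB core -------------------------------------
    rx("r19", "NFkB+IkB",       "IkB_NFkB",      "a6", "association",  "cyto_core"),
    rx("r20", "IkB_NFkB",       "NFkB+IkB",      "d6", "dissociation", "cyto_core"),
    rx("r21", "IKKp+IkB",       "IKKp_IkB",      "a7", "association",  "cyto_core"),
    rx("r22", "IKKp_IkB",       "IKKp+IkB",      "d7", "dissociation", "cyto_core"),
    rx("r23", "IKKp_IkB",       "IKKp_IkBp",     "c5", "catalysis",    "cyto_core"),
    rx("r24", "IKKp_IkBp",      "IKKp+IkBp",     "d9", "dissociation", "cyto_core"),
    rx("r25", "IKKp+IkB_NFkB",  "IKKp_IkB_NFkB", "a8", "association",  "cyto_core"),
    rx("r26", "IKKp_IkB_NFkB",  "IKKp+IkB_NFkB", "d8", "dissociation", "cyto_core"),
    rx("r27", "IKKp_IkB_NFkB",  "IKKp_IkBp_NFkB","c6", "catalysis",    "cyto_core"),
    rx("r28", "IKKp_IkBp_NFkB", "IKKp+IkBp_NFkB","d10","dissociation", "cyto_core"),
    rx("r29", "IkBp",           "",              "g3", "degradation",  "cyto_core"),
    rx("r30", "IkBp_NFkB",      "NFkB",          "g4", "degradation",  "cyto_core"),
    rx("r31", "IkB",            "",              "g5", "degradation",  "cyto_core"),
    rx("r32", "IkB_NFkB",       "NFkB",          "g6", "degradation",  "cyto_core"),
    rx("r33", "NFkBn",          "NFkBn+IkB_mRNA","t1", "synthesis",    "cyto_core"),
    rx("r34", "IkB_mRNA",       "IkB_mRNA+IkB",  "t2", "synthesis",    "cyto_core"),
    rx("r35", "IkB_mRNA",       "",              "g7", "degradation",  "cyto_core"),
    # -- nuclear IkB-NFkB sub-system ---------------------------------------
    rx("r36", "NFkB",           "NFkBn",         "n1", "transport",    "nuclear"),
    rx("r37", "IkB",            "IkBn",          "n2", "transport",    "nuclear"),
    rx("r38", "NFkBn+IkBn",     "IkBn_NFkBn",    "a9", "association",  "nuclear"),
    rx("r39", "IkBn_NFkBn",     "IkB_NFkB",      "e1", "transport",    "nuclear")
  )
}

# Rate constants fixed at their literature values during estimation: the TNFa
# receptor and IKK-cascade sub-systems are not cell-line specific, so their 18
# parameters are frozen and only the 21 constants of the cytoplasmic core and
# nuclear modules are fitted.
FIXED_PARAMS <- c("a1","d1","a2","d2","a3","d3",
                  "a4","d4","c1","a5","d5","c2","c3","c4","b1","b2","c7","c8")

#' Parameters targeted by proteasome inhibition
#'
#' The four rate constants describing proteasome-mediated IkBa destruction:
#' degradation of free phospho-IkBa, of phospho-IkBa bound to NFkB (which
#' releases NFkB), and the constitutive turnover of free IkBa and of the
#' IkBa:NFkB complex. A proteasome inhibitor scales all four by the same
#' Hill-type occupancy factor.
#' @export
PROTEASOME_PARAMS <- c("g3", "g4", "g5", "g6")

# ---------------------------------------------------------------------------

parse_side <- function(s) {
  # "A+2*B" -> named integer vector c(A = 1, B = 2); "" -> empty vector
  s <- trimws(s)
  if (identical(s, "")) return(setNames(integer(0), character(0)))
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  counts <- ifelse(grepl("*", parts, fixed = TRUE),
                   as.integer(sub("\\*.*$", "", parts)), 1L)
  ids <- sub("^[0-9]+\\*", "", parts)
  setNames(as.integer(counts), ids)
}

format_side <- function(v) {
  if (length(v) == 0) return("")
  paste(ifelse(v > 1L, paste0(v, "*", names(v)), names(v)), collapse = "+")
}

#' Build the stoichiometry matrix of a reaction table
#'
#' @param species_ids character vector of species ids (row order).
#' @param reactions reaction data.frame as from [nfkb_reactions()].
#' @return Integer matrix, species x reactions, with signed net counts.
#' @export
stoichiometry_matrix <- function(species_ids, reactions) {
  S <- matrix(0L, nrow = length(species_ids), ncol = nrow(reactions),
              dimnames = list(species_ids, reactions$id))
  for (j in seq_len(nrow(reactions))) {
    re <- parse_side(reactions$reactants[j])
    pr <- parse_side(reactions$products[j])
    for (id in names(re)) S[id, j] <- S[id, j] - re[[id]]
    for (id in names(pr)) S[id, j] <- S[id, j] + pr[[id]]
  }
  S
}

#' Construct a pathway model object
#'
#' Assembles and validates the containers used throughout the package: the
#' species inventory, the mass-action reaction table, the kinetic parameter
#' map with its fixed/free mask, initial concentrations, and the signed
#' stoichiometry matrix.
#'
#' @param species data.frame as from [nfkb_species()].
#' @param reactions data.frame as from [nfkb_reactions()].
#' @param parameters named numeric vector, one value per rate-constant
#'   symbol (units 1/min for unimolecular, 1/(uM min) for bimolecular).
#' @param initial named numeric vector of initial concentrations (uM); any
#'   species missing from the vector starts at zero.
#' @param fixed character vector of parameter symbols excluded from
#'   estimation.
#' @return An object of class `pathway_model`.
#' @export
pathway_model <- function(species, reactions, parameters, initial,
                          fixed = FIXED_PARAMS) {
  stopifnot(!anyDuplicated(species$id), !anyDuplicated(reactions$id))
  if (!all(species$compartment %in% COMPARTMENTS))
    stop("unknown compartment in species table")
  if (!all(species$subsystem %in% SUBSYSTEMS))
    stop("unknown subsystem in species table")
  if (!all(reactions$kind %in% REACTION_KINDS))
    stop("unknown reaction kind")
  referenced <- unique(unlist(lapply(
    c(reactions$reactants, reactions$products),
    function(s) names(parse_side(s)))))
  missing_sp <- setdiff(referenced, species$id)
  if (length(missing_sp))
    stop("reaction references unknown species: ",
         paste(missing_sp, collapse = ", "))
  missing_k <- setdiff(reactions$rate_constant, names(parameters))
  if (length(missing_k))
    stop("missing rate constants: ", paste(missing_k, collapse = ", "))
  init <- setNames(numeric(nrow(species)), species$id)
  if (length(initial)) {
    unknown <- setdiff(names(initial), species$id)
    if (length(unknown))
      stop("initial concentration for unknown species: ",
           paste(unknown, collapse = ", "))
    init[names(initial)] <- initial
  }
  if (any(!is.finite(init)) || any(init < 0))
    stop("initial concentrations must be finite and non-negative")
  structure(list(
    species = species,
    reactions = reactions,
    parameters = parameters[sort(names(parameters))],
    fixed = intersect(fixed, names(parameters)),
    initial = init,
    stoichiometry = stoichiometry_matrix(species$id, reactions)
  ), class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions, ", length(x$parameters),
      " parameters (", length(free_parameters(x)), " free)\n", sep = "")
  invisible(x)
}

#' Free (estimated) parameter symbols of a model
#' @param model a `pathway_model`.
#' @export
free_parameters <- function(model) {
  setdiff(names(model$parameters), model$fixed)
}

#' Build the canonical drug-free NFkB pathway model
#'
#' Returns the 26-species, 39-parameter mass-action model of TNFa-induced
#' NFkB activation with one of the two shipped rate-constant sets:
#' `"fitted"`, the multiple-myeloma-calibrated set used for all drug
#' predictions, or `"prior"`, the literature-scale set whose trajectories
#' show the damped IkB/NFkB oscillations characteristic of published NFkB
#' models.
#'
#' @param parameters `"fitted"`, `"prior"`, or a named numeric vector giving
#'   all 39 rate constants.
#' @param tnfa_dose initial TNFa concentration in uM (0.2 uM is the
#'   stimulation used throughout).
#' @return A `pathway_model`.
#' @export
build_default_model <- function(parameters = "fitted", tnfa_dose = 0.2) {
  if (is.character(parameters)) {
    parameters <- match.arg(parameters, c("fitted", "prior"))
    parameters <- read_parameters(system.file(
      "extdata", paste0("params_", parameters, ".csv"),
      package = "nfkbdrug", mustWork = TRUE))
  }
  init <- default_initial_concentrations()
  init["TNFa"] <- tnfa_dose
  pathway_model(nfkb_species(), nfkb_reactions(), parameters, init)
}

#' Default initial concentrations (uM)
#'
#' Eleven species start at nonzero concentration: the TNFa bolus, the
#' unliganded receptor module (TNFR1, TNFR1A, TRAFs), the resting kinases
#' (IKKK, IKK), and the resting cytoplasmic/nuclear NFkB-IkB pools. All
#' complexes downstream of ligand binding start at zero. Magnitudes are
#' literature-scale (total NFkB moiety 0.91 uM, resting IKKK and IKK pools
#' 0.2 uM each).
#' @export
default_initial_concentrations <- function() {
  read_initial(system.file("extdata", "initial_concentrations.csv",
                           package = "nfkbdrug", mustWork = TRUE))
}

#' Mass-action flux of one reaction (uM/min)
#'
#' The law of mass action: rate constant times the product of reactant
#' concentrations raised to their stoichiometric counts. A reaction with no
#' reactants (synthesis) has flux equal to its rate constant.
#'
#' @param reaction one row of a reaction table.
#' @param state named numeric vector of concentrations (uM).
#' @param params named numeric vector of rate constants.
#' @export
mass_action_flux <- function(reaction, state, params) {
  k <- params[[reaction$rate_constant]]
  if (is.null(k)) stop("unknown rate constant: ", reaction$rate_constant)
  re <- parse_side(reaction$reactants)
  if (length(re) == 0) return(k)
  unname(k * prod(state[names(re)]^re))
}

#' Assemble the ODE right-hand side of a model
#'
#' Returns a derivative function d(state)/dt = S . v(state), with S the
#' signed stoichiometry matrix and v the mass-action flux vector. The
#' returned function has the `deSolve` signature `function(t, state, parms)`
#' and ignores `parms` (rate constants are baked in for speed); it is also
#' callable as `f(t, state)`.
#'
#' @param model a `pathway_model`.
#' @param params optional named vector overriding the model's parameters.
#' @return A function computing `list(dstate)`.
#' @export
assemble_odes <- function(model, params = NULL) {
  p <- model$parameters
  if (!is.null(params)) p[names(params)] <- params
  rxn <- model$reactions
  k <- unname(p[rxn$rate_constant])
  if (anyNA(k)) stop("missing rate constants for some reactions")
  nsp <- nrow(model$species)
  nrx <- nrow(rxn)
  # Factor table: reactant index repeated per stoichiometric count, padded
  # with index nsp+1 which maps to a constant 1 (so flux is a plain product).
  fac <- lapply(rxn$reactants, function(s) {
    re <- parse_side(s)
    rep(match(names(re), model$species$id), times = re)
  })
  max_ord <- max(1L, vapply(fac, length, 1L))
  F <- matrix(nsp + 1L, nrow = nrx, ncol = max_ord)
  for (j in seq_len(nrx))
    if (length(fac[[j]])) F[j, seq_along(fac[[j]])] <- fac[[j]]
  S <- model$stoichiometry
  storage.mode(S) <- "double"
  function(t, state, parms = NULL) {
    s1 <- c(unname(state), 1)
    v <- k
    for (cc in seq_len(max_ord)) v <- v * s1[F[, cc]]
    list(as.vector(S %*% v))
  }
}

# Cache of the structural (parameter-independent) part of packed models,
# keyed by the model's species/reaction inventory. Repeated integrations of
# the same structure (as in fitting, where only rate constants change) then
# skip re-parsing the reaction table.
.pack_cache <- new.env(parent = emptyenv())

# Pack a model (with optional parameter overrides) into the flat numeric
# layout consumed by the compiled mass-action right-hand side in
# src/massaction.c: header (nsp, nrx, max order), rate constants, factor
# index matrix (0 = no factor), stoichiometry matrix.
pack_model <- function(model, params = NULL) {
  p <- model$parameters
  if (!is.null(params)) p[names(params)] <- params
  rxn <- model$reactions
  k <- unname(p[rxn$rate_constant])
  if (anyNA(k)) stop("missing rate constants for some reactions")
  key <- paste(c(model$species$id, rxn$id, rxn$reactants, rxn$products),
               collapse = ";")
  static <- .pack_cache[[key]]
  if (is.null(static)) {
    nsp <- nrow(model$species)
    nrx <- nrow(rxn)
    fac <- lapply(rxn$reactants, function(s) {
      re <- parse_side(s)
      rep(match(names(re), model$species$id), times = re)
    })
    max_ord <- max(1L, vapply(fac, length, 1L))
    fmat <- matrix(0, nrow = nrx, ncol = max_ord)
    for (j in seq_len(nrx))
      if (length(fac[[j]])) fmat[j, seq_along(fac[[j]])] <- fac[[j]]
    static <- list(header = c(nsp, nrx, max_ord),
                   tail = c(as.vector(fmat),
                            as.vector(model$stoichiometry)))
    .pack_cache[[key]] <- static
  }
  as.double(c(static$header, k, static$tail))
}

#' Validate structural properties of a pathway model
#'
#' Checks the structural counts of the canonical model (26 species, 39
#' kinetic parameters, 21 free parameters, 11 nonzero initial
#' concentrations), referential integrity of the reaction table, and the
#' conservation of the NFkB and IKK moieties once synthesis and degradation
#' reactions are removed (computed from the left null space of the reduced
#' stoichiometry matrix).
#'
#' @param model a `pathway_model`.
#' @param expect named numeric vector of expected counts.
#' @return A list with the observed counts, per-check pass flags, conserved
#'   moiety vectors, and an overall `ok` flag.
#' @export
validate_model <- function(model,
                           expect = c(species = 26, parameters = 39,
                                      free = 21, nonzero_init = 11)) {
  counts <- c(species = nrow(model$species),
              reactions = nrow(model$reactions),
              parameters = length(model$parameters),
              free = length(free_parameters(model)),
              nonzero_init = sum(model$initial > 0))
  referenced <- unique(unlist(lapply(
    c(model$reactions$reactants, model$reactions$products),
    function(s) names(parse_side(s)))))
  missing_species <- setdiff(referenced, model$species$id)
  orphan_species <- setdiff(model$species$id, referenced)

  moieties <- conserved_moieties(model)
  nfkb_cons <- moiety_contains(moieties, "NFkBn")
  ikk_cons  <- moiety_contains(moieties, "IKKp")

  checks <- c(expect[names(expect)] == counts[names(expect)],
              referential_integrity = length(missing_species) == 0,
              no_orphan_species = length(orphan_species) == 0,
              nfkb_moiety_conserved = nfkb_cons,
              ikk_moiety_conserved = ikk_cons)
  list(counts = counts, checks = checks,
       missing_species = missing_species, orphan_species = orphan_species,
       moieties = moieties, ok = all(checks))
}

# Conservation laws of the model with synthesis/degradation removed:
# integer-ish basis of the left null space of the reduced stoichiometry.
conserved_moieties <- function(model) {
  keep <- !(model$reactions$kind %in% c("synthesis", "degradation"))
  S <- model$stoichiometry[, keep, drop = FALSE]
  ns <- MASS::Null(S)   # basis of null space of t(S), i.e. y with y'S = 0
  if (length(ns) == 0) return(list())
  lapply(seq_len(ncol(ns)), function(j) setNames(ns[, j], model$species$id))
}

moiety_contains <- function(moieties, species_id) {
  any(vapply(moieties, function(m) abs(m[[species_id]]) > 1e-8, TRUE))
}

#' Total concentration of a conserved moiety along a state
#' @param model a `pathway_model`.
#' @param state named concentration vector.
#' @param members species ids carrying the moiety (weights of 1 each).
#' @export
moiety_total <- function(model, state, members) {
  sum(state[members])
}

#' Species carrying the NFkB moiety
#' @export
NFKB_MOIETY <- c("NFkB", "IkB_NFkB", "IKKp_IkB_NFkB", "IKKp_IkBp_NFkB",
                 "IkBp_NFkB", "NFkBn", "IkBn_NFkBn")

#' Species carrying the IKK moiety
#' @export
IKK_MOIETY <- c("IKK", "IKKKp_IKK", "IKKp", "IKKp_IkB", "IKKp_IkB_NFkB",
                "IKKp_IkBp", "IKKp_IkBp_NFkB")
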