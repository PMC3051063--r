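#' @importFrom utils read.csv write.csv
NULL

#' Read / write a rate-constant file
#'
#' Plain CSV with columns `parameter`, `value`, `fixed` (`fixed` or `free`).
#' Units are 1/min for unimolecular and 1/(uM min) for bimolecular constants.
#'
#' @param path file path.
#' @return Named numeric vector with attribute `fixed` (character vector of
#'   fixed symbols).
#' @export
read_parameters <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("parameter", "value", "fixed") %in% names(df)))
  p <- setNames(df$value, df$parameter)
  attr(p, "fixed") <- df$parameter[df$fixed == "fixed"]
  p
}

#' @rdname read_parameters
#' @param params named numeric vector of rate constants.
#' @param fixed character vector of fixed parameter symbols.
#' @export
write_parameters <- function(params, path, fixed = FIXED_PARAMS) {
  df <- data.frame(parameter = names(params), value = unname(params),
                   fixed = ifelse(names(params) %in% fixed, "fixed", "free"))
  df <- df[order(df$parameter), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an initial-concentration file
#'
#' CSV with columns `species`, `concentration_uM`; species absent from the
#' file start at zero.
#' @param path file path.
#' @export
read_initial <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "concentration_uM") %in% names(df)))
  if (any(df$concentration_uM < 0))
    stop("negative initial concentration for: ",
         paste(df$species[df$concentration_uM < 0], collapse = ", "))
  setNames(df$concentration_uM, df$species)
}

#' @rdname read_initial
#' @param init named numeric vector (uM).
#' @export
write_initial <- function(init, path) {
  df <- data.frame(species = names(init), concentration_uM = unname(init))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reaction-table file
#'
#' CSV mirror of [nfkb_reactions()]: columns `id`, `reactants`, `products`,
#' `rate_constant`, `kind`, `subsystem`.
#' @param path file path.
#' @export
read_reactions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("id", "reactants", "products", "rate_constant", "kind", "subsystem")
  stopifnot(all(need %in% names(df)))
  df$reactants[is.na(df$reactants)] <- ""
  df$products[is.na(df$products)] <- ""
  df[need]
}

#' @rdname read_reactions
#' @param reactions reaction data.frame.
#' @export
write_reactions <- function(reactions, path) {
  write.csv(reactions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a time-course dataset
#'
#' Long CSV with columns `observable` (`IkB_cyt` or `NFkB_nuc`), `time_min`,
#' `value` (uM), `replicate` (0 denotes the replicate mean used for
#' fitting).
#' @param path file path.
#' @return A `timecourse_dataset` (see [timecourse_dataset()]).
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("observable", "time_min", "value", "replicate") %in% names(df)))
  bad <- which(df$value < 0)
  if (length(bad))
    stop("negative concentration at row ", bad[1], " (",
         df$observable[bad[1]], ", t=", df$time_min[bad[1]], ")")
  means <- df[df$replicate == 0, ]
  ikb  <- means[means$observable == "IkB_cyt", ]
  nfkb <- means[means$observable == "NFkB_nuc", ]
  timecourse_dataset(
    ikb_times = ikb$time_min, ikb_values = ikb$value,
    nfkb_times = nfkb$time_min, nfkb_values = nfkb$value,
    replicates = df[df$replicate > 0, ],
    provenance = "file")
}

#' @rdname read_dataset
#' @param dataset a `timecourse_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  means <- rbind(
    data.frame(observable = "IkB_cyt", time_min = dataset$ikb_times,
               value = dataset$ikb_values, replicate = 0),
    data.frame(observable = "NFkB_nuc", time_min = dataset$nfkb_times,
               value = dataset$nfkb_values, replicate = 0))
  out <- rbind(means, dataset$replicates[names(means)])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated time course as long-format CSV
#' @param tc a `timecourse` as returned by [integrate_model()].
#' @param path file path.
#' @export
write_timecourse <- function(tc, path) {
  long <- data.frame(
    time = rep(tc$times, times = ncol(tc$states)),
    species = rep(colnames(tc$states), each = length(tc$times)),
    concentration = as.vector(tc$states))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a steady-state result as JSON
#' @param ss a `steady_state_result`.
#' @param path file path.
#' @export
write_steady_state <- function(ss, path) {
  jsonlite::write_json(
    list(state = as.list(ss$state), converged = ss$converged,
         oscillatory = ss$oscillatory, t_reached = ss$t_reached,
         residual = ss$residual),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a model as SBML Level 3 Version 2
#'
#' Writes species (with compartments and initial concentrations), parameters
#' and mass-action kinetic laws. The document is plain SBML core; it is
#' intended for interoperability with pathway tools, not round-tripping of
#' package-internal metadata (sub-system tags travel as SBO-free annotations
#' via species name only).
#'
#' @param model a `pathway_model`.
#' @param path output file.
#' @export
export_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "nfkb_pathway_mm",
                             name = "TNFa-induced NFkB pathway")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (comp in COMPARTMENTS)
    xml2::xml_add_child(lc, "compartment", id = comp, constant = "true",
                        spatialDimensions = "3", size = "1")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    sp <- model$species[i, ]
    xml2::xml_add_child(
      ls, "species", id = sp$id, name = sp$display_name,
      compartment = sp$compartment,
      initialConcentration = format(model$initial[[sp$id]], digits = 12),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (nm in names(model$parameters))
    xml2::xml_add_child(lp, "parameter", id = nm,
                        value = format(model$parameters[[nm]], digits = 12),
                        constant = "true")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    rxn <- model$reactions[j, ]
    xr <- xml2::xml_add_child(lr, "reaction", id = rxn$id,
                              reversible = "false")
    re <- parse_side(rxn$reactants)
    pr <- parse_side(rxn$products)
    if (length(re)) {
      lre <- xml2::xml_add_child(xr, "listOfReactants")
      for (id in names(re))
        xml2::xml_add_child(lre, "speciesReference", species = id,
                            stoichiometry = as.character(re[[id]]),
                            constant = "true")
    }
    if (length(pr)) {
      lpr <- xml2::xml_add_child(xr, "listOfProducts")
      for (id in names(pr))
        xml2::xml_add_child(lpr, "speciesReference", species = id,
                            stoichiometry = as.character(pr[[id]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(xr, "kineticLaw")
    mml <- xml2::xml_add_child(kl, "math",
                               xmlns = "http://www.w3.org/1998/Math/MathML")
    terms <- c(rxn$rate_constant, rep(names(re), times = re))
    if (length(terms) == 1) {
      xml2::xml_add_child(mml, "ci", terms)
    } else {
      ap <- xml2::xml_add_child(mml, "apply")
      xml2::xml_add_child(ap, "times")
      for (tm in terms) xml2::xml_add_child(ap, "ci", tm)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Verify that reader/writer pairs are inverses on a model's artifacts
#'
#' Writes the model's reaction table, parameters and initial concentrations
#' to a scratch directory, reads them back, rewrites them, and compares
#' bytes. Used by tests and the pipeline self-check.
#'
#' @param model a `pathway_model`.
#' @param dir scratch directory.
#' @return list of logical flags, one per artifact.
#' @export
read_write_roundtrips <- function(model, dir = tempdir()) {
  same_bytes <- function(write1, read1, write2) {
    p1 <- tempfile(tmpdir = dir, fileext = ".csv")
    p2 <- tempfile(tmpdir = dir, fileext = ".csv")
    write1(p1); write2(read1(p1), p2)
    identical(readBin(p1, "raw", file.size(p1)),
              readBin(p2, "raw", file.size(p2)))
  }
  list(
    reactions = same_bytes(
      function(p) write_reactions(model$reactions, p), read_reactions,
      write_reactions),
    parameters = same_bytes(
      function(p) write_parameters(model$parameters, p, model$fixed),
      read_parameters,
      function(x, p) write_parameters(x, p, attr(x, "fixed"))),
    initial = same_bytes(
      function(p) write_initial(model$initial, p), read_initial,
      write_initial)
  )
}
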