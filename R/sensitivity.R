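#' Local sensitivity coefficient of the steady nuclear NFkB output
#'
#' Perturbs one kinetic parameter or one initial concentration by
#' `delta_fraction` (default 1%) in each direction, recomputes the steady
#' output Y (nuclear NFkB), and reports the normalized coefficient
#' `S = (dY/Y) / (dp/p)` per direction plus their mean.
#'
#' @param model a `pathway_model`.
#' @param target parameter symbol or species id.
#' @param kind `"kinetic"` or `"initial"`.
#' @param delta_fraction relative perturbation size.
#' @param baseline optional precomputed baseline output (uM).
#' @param ... passed to [steady_state()].
#' @return list with `S_up`, `S_down`, `S_mean`,
#'   `output_change_percent` (max |dY|/Y over both directions, in %), and
#'   `flagged` (TRUE when a perturbed system failed to produce an output).
#' @export
sensitivity_coefficient <- function(model, target,
                                    kind = c("kinetic", "initial"),
                                    delta_fraction = 0.01, baseline = NULL,
                                    ...) {
  kind <- match.arg(kind)
  if (is.null(baseline)) baseline <- nuclear_nfkb_output(model, ...)
  out_at <- function(mult) {
    m <- model
    if (kind == "kinetic") {
      if (!(target %in% names(m$parameters)))
        stop("unknown parameter: ", target)
      m$parameters[[target]] <- m$parameters[[target]] * mult
    } else {
      if (!(target %in% names(m$initial)))
        stop("unknown species: ", target)
      m$initial[[target]] <- m$initial[[target]] * mult
    }
    tryCatch(nuclear_nfkb_output(m, ...), error = function(e) NA_real_)
  }
  y_up <- out_at(1 + delta_fraction)
  y_dn <- out_at(1 - delta_fraction)
  s_up <- (y_up - baseline) / baseline / delta_fraction
  s_dn <- (baseline - y_dn) / baseline / delta_fraction
  list(S_up = s_up, S_down = s_dn, S_mean = mean(c(s_up, s_dn)),
       output_change_percent =
         100 * max(abs(c(y_up, y_dn) - baseline), na.rm = TRUE) / baseline,
       flagged = is.na(y_up) || is.na(y_dn))
}

#' Full local sensitivity scan
#'
#' One-at-a-time 1% perturbation of all 39 kinetic parameters and the 11
#' nonzero initial concentrations (50 targets, both directions), against
#' the steady nuclear NFkB output.
#'
#' @param model a `pathway_model`.
#' @param delta_fraction relative perturbation size.
#' @param ... passed to [steady_state()].
#' @return A data.frame (`sensitivity_table`) with one row per target:
#'   `target`, `kind`, `subsystem`, `S_up`, `S_down`, `S_mean`,
#'   `output_change_percent`, `flagged`, sorted by |S_mean| descending.
#' @export
sensitivity_scan <- function(model, delta_fraction = 0.01, ...) {
  baseline <- nuclear_nfkb_output(model, ...)
  par_sub <- setNames(model$reactions$subsystem,
                      model$reactions$rate_constant)
  targets <- rbind(
    data.frame(target = names(model$parameters), kind = "kinetic",
               subsystem = unname(par_sub[names(model$parameters)])),
    data.frame(target = names(model$initial)[model$initial > 0],
               kind = "initial",
               subsystem = model$species$subsystem[
                 match(names(model$initial)[model$initial > 0],
                       model$species$id)]))
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    s <- sensitivity_coefficient(model, targets$target[i], targets$kind[i],
                                 delta_fraction, baseline = baseline, ...)
    cbind(targets[i, , drop = FALSE], as.data.frame(s))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-abs(tab$S_mean)), ]
  rownames(tab) <- NULL
  attr(tab, "baseline_output") <- baseline
  class(tab) <- c("sensitivity_table", "data.frame")
  tab
}

#' Write a sensitivity table to CSV
#' @param tab a `sensitivity_table`.
#' @param path file path.
#' @export
write_sensitivity <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
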