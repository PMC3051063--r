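#' Configuration for a full prediction run
#'
#' Bundles the knobs of the end-to-end workflow: model parameter set, fit
#' settings, dose ranges for the combination scans (defaults 0-4 uM for D2,
#' 0-0.02 uM for D3, 0-1 uM for D4), grid resolution, Bliss thresholds, and
#' output directory.
#'
#' @param parameters `"fitted"`, `"prior"`, or named vector (see
#'   [build_default_model()]).
#' @param fit NULL to skip refitting, or a list with `n_starts`, `seed`,
#'   `target_error`, `max_evals`.
#' @param dose_ranges named list of maximal doses (uM) per drug.
#' @param n_levels combination-grid levels per drug.
#' @param n_curve_points points per single-drug curve.
#' @param thresholds c(down, up) Bliss classification thresholds.
#' @param isobole_x inhibition levels for the isobolograms.
#' @param out_dir output directory.
#' @param seed seed recorded in the manifest and used by any stochastic
#'   stage.
#' @return A `run_config`.
#' @export
run_config <- function(parameters = "fitted", fit = NULL,
                       dose_ranges = list(D2 = 4, D3 = 0.02, D4 = 1),
                       n_levels = 10, n_curve_points = 13,
                       thresholds = c(down = 0.99, up = 1.01),
                       isobole_x = c(0.25, 0.5), out_dir = "results",
                       seed = 1) {
  if (!(thresholds[1] < thresholds[2]))
    stop("thresholds must satisfy down < up")
  if (any(unlist(dose_ranges) <= 0)) stop("dose ranges must be positive")
  structure(list(parameters = parameters, fit = fit,
                 dose_ranges = dose_ranges, n_levels = n_levels,
                 n_curve_points = n_curve_points, thresholds = thresholds,
                 isobole_x = isobole_x, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full prediction workflow
#'
#' Build and validate the model, optionally refit its free parameters to a
#' dataset, run the sensitivity scan, compute the D1 null-effect report and
#' the D2/D3/D4 single-drug curves, the three two-drug Bliss grids, and the
#' Loewe isobolograms; write every artifact under the configured output
#' directory together with a JSON manifest of files, seeds and settings.
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config a `run_config`.
#' @param dataset optional `timecourse_dataset` for the fit stage.
#' @return The manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  model <- stage("build", {
    m <- build_default_model(config$parameters)
    v <- validate_model(m)
    if (!v$ok) stop("model validation failed")
    m
  })
  drugs <- default_drugs(model$parameters)

  if (!is.null(config$fit)) {
    fit <- stage("fit", {
      if (is.null(dataset)) stop("fit requested but no dataset supplied")
      do.call(multistart_fit,
              c(list(dataset = dataset, model = model), config$fit))
    })
    model <- with_free_parameters(model, fit$best_params)
    drugs <- default_drugs(model$parameters)
    p <- file.path(config$out_dir, "fitted_parameters.csv")
    write_parameters(model$parameters, p, model$fixed)
    outputs$fit <- p
  }

  sens <- stage("sensitivity", sensitivity_scan(model))
  outputs$sensitivity <- file.path(config$out_dir, "sensitivity.csv")
  write_sensitivity(sens, outputs$sensitivity)

  curves <- stage("dose_response", {
    out <- list()
    for (id in names(config$dose_ranges)) {
      doses <- seq(0, config$dose_ranges[[id]],
                   length.out = config$n_curve_points)
      out[[id]] <- dose_response_curve(model, id, doses, drugs)
      p <- file.path(config$out_dir, sprintf("curve_%s.csv", id))
      write.csv(as.data.frame(out[[id]]), p, row.names = FALSE,
                quote = FALSE)
      # the stage expression evaluates in this function's frame, so plain
      # assignment updates the manifest accumulator
      outputs[[paste0("curve_", id)]] <- p
    }
    out
  })

  outputs$d1_report <- stage("d1_null_effect", {
    doses <- c(0, 1, 10, 100, 500, 1000)
    cv <- dose_response_curve(model, "D1", doses, drugs)
    p <- file.path(config$out_dir, "d1_null_effect.csv")
    write.csv(as.data.frame(cv), p, row.names = FALSE, quote = FALSE)
    p
  })

  pairs <- utils::combn(names(config$dose_ranges), 2, simplify = FALSE)
  maps <- stage("combination_grids", {
    out <- list()
    for (pr in pairs) {
      map <- combination_grid(
        model, pr[1], pr[2],
        rangeA = config$dose_ranges[[pr[1]]],
        rangeB = config$dose_ranges[[pr[2]]],
        n_levels = config$n_levels, drugs = drugs,
        threshold_down = config$thresholds[1],
        threshold_up = config$thresholds[2])
      files <- write_synergy_map(map, config$out_dir)
      out[[paste(pr, collapse = "_")]] <- map
      outputs[[paste0("grid_", paste(pr, collapse = "_"))]] <- files
    }
    out
  })

  stage("isobolograms", {
    for (pr in pairs) {
      for (x in config$isobole_x) {
        cA <- curves[[pr[1]]]; cB <- curves[[pr[2]]]
        if (max(cA$inhibition) < x || max(cB$inhibition) < x) next
        iso <- loewe_isobole(model, pr[1], pr[2], x, cA, cB, drugs = drugs)
        p <- file.path(config$out_dir,
                       sprintf("isobole_%s_%s_x%02d.csv", pr[1], pr[2],
                               round(100 * x)))
        write_isobologram(iso, p)
        outputs[[sprintf("isobole_%s_%s_x%02d", pr[1], pr[2],
                         round(100 * x))]] <- p
      }
    }
    NULL
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("nfkbdrug")),
    seed = config$seed,
    settings = config[c("parameters", "n_levels", "n_curve_points",
                        "isobole_x")],
    thresholds = as.list(config$thresholds),
    dose_ranges = config$dose_ranges,
    outputs = outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
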