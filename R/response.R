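#' Inhibition rate of the nuclear NFkB output
#'
#' `I = (Y0 - Y) / Y0`, with Y0 the drug-free steady nuclear NFkB and Y the
#' steady output under the dose configuration.
#'
#' @param model drug-free `pathway_model`.
#' @param doses named dose vector (uM), see [nuclear_nfkb_output()].
#' @param drugs drug specification list.
#' @param control_output optional precomputed Y0 (uM); recomputed from the
#'   model when NULL.
#' @param ... passed to [steady_state()].
#' @return Inhibition fraction (1 = complete suppression).
#' @export
inhibition_rate <- function(model, doses, drugs = default_drugs(),
                            control_output = NULL, ...) {
  if (is.null(control_output))
    control_output <- nuclear_nfkb_output(model, ...)
  if (control_output <= 0)
    stop("control output Y0 must be positive")
  y <- nuclear_nfkb_output(model, doses, drugs, ...)
  (control_output - y) / control_output
}

#' Single-drug dose-response curve
#'
#' Evaluates [inhibition_rate()] over a dose grid and classifies the curve
#' shape: `"sigmoidal"` when the response accelerates at low dose (positive
#' curvature near the origin, as a Hill curve with n > 1), `"hyperbolic"`
#' otherwise.
#'
#' @param model drug-free `pathway_model`.
#' @param drug_id drug id in `drugs`.
#' @param doses non-negative increasing dose grid (uM).
#' @param drugs drug specification list.
#' @param ... passed to [steady_state()].
#' @return A `dose_response_curve`: data.frame (`dose`, `inhibition`) with
#'   attributes `drug`, `control_output`, `shape`, `monotone`.
#' @export
dose_response_curve <- function(model, drug_id, doses,
                                drugs = default_drugs(), ...) {
  stopifnot(all(doses >= 0), !is.unsorted(doses))
  y0 <- nuclear_nfkb_output(model, ...)
  inh <- vapply(doses, function(d) {
    if (d == 0) return(0)
    inhibition_rate(model, setNames(d, drug_id), drugs,
                    control_output = y0, ...)
  }, numeric(1))
  out <- data.frame(dose = doses, inhibition = inh)
  attr(out, "drug") <- drug_id
  attr(out, "control_output") <- y0
  attr(out, "monotone") <- !is.unsorted(inh - 1e-9 * seq_along(inh))
  attr(out, "shape") <- curve_shape(doses, inh)
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

# Low-dose curvature heuristic: compare the early response with the chord
# from the origin to the half-way point (0,0)-(d50, ymax/2). A concave
# (hyperbolic, Hill n = 1) curve lies above that chord at low dose; a
# sigmoidal curve (Hill n > 1, convex start) lies below it. For an exact
# Hill curve the mean low-dose deviation is +0.08*ymax at n = 1 and
# -0.05*ymax at n = 2, so the sign separates the two shapes.
curve_shape <- function(doses, inh) {
  pos <- doses > 0 & inh > 0
  if (sum(pos) < 3 || max(inh) <= 0.05) return("flat")
  d <- doses[pos]; y <- inh[pos]
  ymax <- max(y)
  d50 <- stats::approx(y, d, xout = ymax / 2, ties = "ordered")$y
  # no sampled dose below the half-point (coarse grid): curvature at low
  # dose is unobservable, fall back to the concave label
  if (is.na(d50) || !any(d <= d50)) return("hyperbolic")
  low <- d <= d50
  chord <- (ymax / 2) * d[low] / d50
  if (mean(y[low] - chord) < 0) "sigmoidal" else "hyperbolic"
}

#' Invert a dose-response curve at inhibition level x
#'
#' Smallest dose achieving inhibition `x`, by monotone linear interpolation
#' between the bracketing grid points.
#'
#' @param curve a `dose_response_curve`.
#' @param x inhibition level in (0, 1).
#' @return Dose (uM).
#' @export
ic_x <- function(curve, x) {
  stopifnot(x > 0, x < 1)
  inh <- curve$inhibition
  if (max(inh) < x)
    stop(sprintf("inhibition %.3f not achievable (curve maximum %.3f)",
                 x, max(inh)))
  i <- which(inh >= x)[1]
  if (i == 1) return(curve$dose[1])
  d0 <- curve$dose[i - 1]; d1 <- curve$dose[i]
  y0 <- inh[i - 1]; y1 <- inh[i]
  d0 + (x - y0) / (y1 - y0) * (d1 - d0)
}

#' Bliss combination index
#'
#' `CI = (E1 + E2 - E1 * E2) / E12`: the Bliss-independent expected combined
#' inhibition over the observed combined inhibition. CI below 1 indicates
#' synergy (the combination outperforms independence), above 1 antagonism.
#'
#' @param E1,E2 single-drug inhibition fractions in [0, 1].
#' @param E12 combined inhibition fraction in [0, 1].
#' @return CI, or `NA` (undefined) when `E12 = 0`.
#' @export
bliss_ci <- function(E1, E2, E12) {
  vals <- c(E1, E2, E12)
  if (any(vals < -1e-9 | vals > 1 + 1e-9))
    stop("inhibition fractions must lie in [0, 1]")
  ifelse(E12 == 0, NA_real_, (E1 + E2 - E1 * E2) / E12)
}

#' Classify a Bliss combination index
#'
#' Synergy below `threshold_down`, antagonism above `threshold_up`,
#' additive in between (defaults 0.99 / 1.01: a 1% noise band around exact
#' independence); `NA` passes through as `"undefined"`.
#'
#' @param ci Bliss CI (vectorized).
#' @param threshold_down,threshold_up classification thresholds.
#' @return character vector.
#' @export
classify_bliss <- function(ci, threshold_down = 0.99, threshold_up = 1.01) {
  stopifnot(threshold_down < threshold_up)
  out <- ifelse(is.na(ci), "undefined",
         ifelse(ci < threshold_down, "synergy",
         ifelse(ci > threshold_up, "antagonism", "additive")))
  out
}

#' Two-drug Bliss combination-index grid
#'
#' Doses for each drug are the `n_levels` positive multiples of
#' `range/n_levels` (dose zero is excluded: CI is undefined at zero effect,
#' and the axes are covered by the standalone curves). Single-drug effects
#' are computed once per level and reused across the grid; each cell runs
#' one combined simulation.
#'
#' @param model drug-free `pathway_model`.
#' @param drugA,drugB drug ids.
#' @param rangeA,rangeB maximal doses (uM).
#' @param n_levels dose levels per drug (100 reproduces the full 10,000-cell
#'   scan; scaled-down grids use 10).
#' @param drugs drug specification list.
#' @param threshold_down,threshold_up Bliss classification thresholds.
#' @param ... passed to [steady_state()].
#' @return A `synergy_map`: list with dose vectors `dosesA`, `dosesB`,
#'   single-drug effects `E1`, `E2`, matrices `E12`, `ci` and `class`
#'   (A levels x B levels), and metadata.
#' @export
combination_grid <- function(model, drugA, drugB, rangeA, rangeB,
                             n_levels = 100, drugs = default_drugs(),
                             threshold_down = 0.99, threshold_up = 1.01,
                             ...) {
  stopifnot(rangeA > 0, rangeB > 0, n_levels >= 2,
            threshold_down < threshold_up)
  dosesA <- seq_len(n_levels) * rangeA / n_levels
  dosesB <- seq_len(n_levels) * rangeB / n_levels
  y0 <- nuclear_nfkb_output(model, ...)
  eff <- function(id, d)
    inhibition_rate(model, setNames(d, id), drugs, control_output = y0, ...)
  E1 <- vapply(dosesA, function(d) eff(drugA, d), numeric(1))
  E2 <- vapply(dosesB, function(d) eff(drugB, d), numeric(1))
  E12 <- matrix(NA_real_, n_levels, n_levels)
  for (i in seq_len(n_levels)) {
    for (j in seq_len(n_levels)) {
      E12[i, j] <- tryCatch(
        inhibition_rate(model, setNames(c(dosesA[i], dosesB[j]),
                                        c(drugA, drugB)),
                        drugs, control_output = y0, ...),
        error = function(e) NA_real_)
    }
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  ci <- (outer(clamp01(E1), clamp01(E2),
               function(a, b) a + b - a * b)) / E12
  ci[!is.na(E12) & E12 == 0] <- NA_real_
  cls <- matrix(classify_bliss(ci, threshold_down, threshold_up),
                n_levels, n_levels)
  cls[is.na(E12)] <- "failed"
  structure(list(drugA = drugA, drugB = drugB, dosesA = dosesA,
                 dosesB = dosesB, E1 = E1, E2 = E2, E12 = E12, ci = ci,
                 class = cls, control_output = y0,
                 thresholds = c(down = threshold_down, up = threshold_up)),
            class = "synergy_map")
}

#' Cell-class counts of a synergy map
#' @param map a `synergy_map`.
#' @export
synergy_class_counts <- function(map) {
  table(factor(map$class,
               levels = c("synergy", "additive", "antagonism",
                          "undefined", "failed")))
}

#' Write a synergy map (matrix CSVs + JSON metadata)
#' @param map a `synergy_map`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_synergy_map <- function(map, dir, prefix = paste0(map$drugA, "_",
                                                        map$drugB)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wmat <- function(m, what) {
    df <- as.data.frame(m)
    names(df) <- sprintf("%s_%g", map$drugB, map$dosesB)
    df <- cbind(setNames(data.frame(map$dosesA),
                         sprintf("%s_dose", map$drugA)), df)
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, what))
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(wmat(map$E12, "E12"), wmat(map$ci, "ci"),
             wmat(map$class, "class"))
  meta <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(
    list(drugA = map$drugA, drugB = map$drugB,
         control_output = map$control_output,
         thresholds = as.list(map$thresholds),
         class_counts = as.list(synergy_class_counts(map))),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}

#' Loewe isobologram along fixed-ratio rays
#'
#' For `resolution` dose-ratio rays between the two drug axes, bisects the
#' combined dose along each ray for the total inhibition `x`, giving the
#' iso-effect contour; each contour point carries the Loewe combination
#' index `CI = d1/ICx1 + d2/ICx2`. CI below 1 (contour bowing inward)
#' indicates Loewe synergy.
#'
#' @param model drug-free `pathway_model`.
#' @param drugA,drugB drug ids.
#' @param x inhibition level in (0, 1), achievable by both drugs alone.
#' @param curveA,curveB single-drug `dose_response_curve`s spanning `x`
#'   (used for the ICx anchors and bracketing).
#' @param resolution number of interior rays.
#' @param drugs drug specification list.
#' @param tol_x bisection tolerance on inhibition.
#' @param ... passed to [steady_state()].
#' @return An `isobologram`: data.frame (`d1`, `d2`, `loewe_ci`) with
#'   attributes `x`, `icx` (the two single-drug ICx doses).
#' @export
loewe_isobole <- function(model, drugA, drugB, x, curveA, curveB,
                          resolution = 7, drugs = default_drugs(),
                          tol_x = 0.002, ...) {
  stopifnot(x > 0, x < 1)
  ic1 <- ic_x(curveA, x)
  ic2 <- ic_x(curveB, x)
  y0 <- attr(curveA, "control_output")
  eff <- function(d1, d2)
    inhibition_rate(model, setNames(c(d1, d2), c(drugA, drugB)), drugs,
                    control_output = y0, ...)
  # interior rays parameterized by the fraction of each drug's ICx scale
  fracs <- seq(0, 1, length.out = resolution + 2)[-c(1, resolution + 2)]
  pts <- lapply(fracs, function(fr) {
    # ray direction in ICx-normalized units: (fr, 1 - fr)
    f_of_s <- function(s) eff(s * fr * ic1, s * (1 - fr) * ic2)
    lo <- 0; hi <- 1
    f_hi <- f_of_s(hi)
    it <- 0
    while (f_hi < x && it < 12) {  # expand if the ray undershoots
      lo <- hi; hi <- hi * 2; f_hi <- f_of_s(hi); it <- it + 1
    }
    if (f_hi < x) return(NULL)
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      fm <- f_of_s(mid)
      if (abs(fm - x) < tol_x) { lo <- hi <- mid; break }
      if (fm < x) lo <- mid else hi <- mid
    }
    s <- (lo + hi) / 2
    data.frame(d1 = s * fr * ic1, d2 = s * (1 - fr) * ic2,
               loewe_ci = s * fr + s * (1 - fr))
  })
  contour <- do.call(rbind, pts)
  contour <- rbind(data.frame(d1 = ic1, d2 = 0, loewe_ci = 1),
                   contour,
                   data.frame(d1 = 0, d2 = ic2, loewe_ci = 1))
  attr(contour, "x") <- x
  attr(contour, "icx") <- c(ic1, ic2)
  class(contour) <- c("isobologram", "data.frame")
  contour
}

#' Write an isobologram to CSV
#' @param iso an `isobologram`.
#' @param path file path.
#' @export
write_isobologram <- function(iso, path) {
  write.csv(as.data.frame(iso), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
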