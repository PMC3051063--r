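# Run deSolve::lsoda on the compiled generic mass-action right-hand side
# (src/massaction.c), after installing the packed model for the solver.
ma_lsoda <- function(packed, y0, times, rtol, atol) {
  .Call("massaction_set", packed, PACKAGE = "nfkbdrug")
  deSolve::lsoda(y = y0, times = times, func = "massaction_derivs",
                 dllname = "nfkbdrug", initfunc = NULL, parms = NULL,
                 rtol = rtol, atol = atol, maxsteps = 50000)
}

#' Integrate a pathway model over time
#'
#' Wraps a stiff-capable implicit solver (`deSolve::lsoda`) around the
#' model's compiled mass-action right-hand side (the same derivative as
#' [assemble_odes()] evaluates in R). Default
#' tolerances are tight (rtol 1e-8, atol 1e-10 uM) so that downstream
#' steady-state readouts are solver-robust. Concentrations more negative
#' than -1e-9 uM abort with an error; smaller negative excursions are
#' clipped to zero in the returned states.
#'
#' @param model a `pathway_model`.
#' @param times strictly increasing vector of output times (min).
#' @param params optional named overrides of the model's rate constants.
#' @param init optional named overrides / full replacement of the initial
#'   state (uM). A partial named vector overrides those species only.
#' @param rtol,atol solver tolerances.
#' @return A `timecourse`: list with `times`, `states` (time x species
#'   matrix), and `metadata`.
#' @export
integrate_model <- function(model, times, params = NULL, init = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  if (length(times) < 1 || is.unsorted(times, strictly = TRUE))
    stop("times must be non-empty and strictly increasing")
  y0 <- model$initial
  if (!is.null(init)) {
    if (is.null(names(init)) && length(init) == length(y0)) {
      y0[] <- init
    } else {
      y0[names(init)] <- init
    }
  }
  if (any(y0 < 0)) stop("initial state must be non-negative")
  packed <- pack_model(model, params)
  t0_extra <- times[1] != 0
  tt <- if (t0_extra) c(0, times) else times
  out <- ma_lsoda(packed, y0, tt, rtol, atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integration failed near t=%.3f min", max(out[, "time"])))
  states <- out[, -1, drop = FALSE]
  if (t0_extra) states <- states[-1, , drop = FALSE]
  if (min(states) < -1e-9)
    stop(sprintf("negative concentration (%.3e) produced by the integrator",
                 min(states)))
  states[states < 0] <- 0
  rownames(states) <- NULL
  structure(list(times = times, states = states,
                 metadata = list(rtol = rtol, atol = atol,
                                 solver = "lsoda")),
            class = "timecourse")
}

#' Concentration of one species along a time course
#' @param tc a `timecourse`.
#' @param species species id.
#' @export
species_trace <- function(tc, species) {
  tc$states[, species]
}

#' Drive a model to its steady output
#'
#' Integrates forward in windows until the maximum absolute derivative
#' drops below `tol`, or until a sustained oscillation of the nuclear NFkB
#' readout is detected, or until `t_max`. A sustained oscillation (tail
#' extrema of nuclear NFkB varying by more than 1% of their mean while the
#' residual stays high) is reported via `oscillatory = TRUE` with the
#' tail time-average as the state, so that both the calibrated
#' (converging) and literature-prior (oscillating) parameter sets have a
#' well-defined steady output.
#'
#' @inheritParams integrate_model
#' @param tol residual tolerance on max |d state/dt| (uM/min).
#' @param t_max integration horizon (min).
#' @param window length of each integration window (min).
#' @return A `steady_state_result`: `state`, `converged`, `oscillatory`,
#'   `t_reached`, `residual`.
#' @export
steady_state <- function(model, params = NULL, init = NULL, tol = 1e-6,
                         t_max = 1e5, window = 500, rtol = 1e-8,
                         atol = 1e-10) {
  stopifnot(tol > 0)
  packed <- pack_model(model, params)
  y <- model$initial
  if (!is.null(init)) y[names(init)] <- init
  t_now <- 0
  dt_grid <- 2  # output resolution within a window, for extremum detection
  tail_trace <- NULL
  while (t_now < t_max) {
    t_end <- min(t_now + window, t_max)
    tt <- seq(t_now, t_end, by = dt_grid)
    if (tt[length(tt)] < t_end) tt <- c(tt, t_end)
    out <- ma_lsoda(packed, y, tt, rtol, atol)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integration failed near t=%.1f min", t_now))
    states <- out[, -1, drop = FALSE]
    y <- states[nrow(states), ]
    t_now <- t_end
    resid <- max(abs(.Call("massaction_eval", packed, as.double(y),
                           PACKAGE = "nfkbdrug")))
    if (resid <= tol) {
      y[y < 0] <- 0
      return(structure(list(state = y, converged = TRUE,
                            oscillatory = FALSE, t_reached = t_now,
                            residual = resid),
                       class = "steady_state_result"))
    }
    tail_trace <- rbind(utils::tail(tail_trace, 2 * nrow(states)), states)
  }
  # Not converged by t_max: inspect the stored tail for oscillation.
  nn <- tail_trace[, "NFkBn"]
  n_keep <- max(10L, floor(length(nn) * 0.5))
  nn_tail <- utils::tail(nn, n_keep)
  ext <- local_extrema(nn_tail)
  amp_ok <- mean(nn_tail) > 0 &&
    (max(nn_tail) - min(nn_tail)) / mean(nn_tail) > 0.01
  if (length(ext$maxima) >= 2 && amp_ok) {
    st_tail <- utils::tail(tail_trace, n_keep)
    avg <- colMeans(st_tail)
    avg[avg < 0] <- 0
    return(structure(list(state = avg, converged = FALSE,
                          oscillatory = TRUE, t_reached = t_max,
                          residual = resid),
                     class = "steady_state_result"))
  }
  stop(sprintf(paste0("no steady state or sustained oscillation by t_max=",
                      "%g min (residual %.3e uM/min)"), t_max, resid))
}

# Indices of interior local maxima/minima of a numeric vector.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1
  turns <- which(diff(s) != 0) + 1L
  list(maxima = turns[d[turns - 1] > 0], minima = turns[d[turns - 1] < 0])
}

#' Steady nuclear NFkB output under a drug configuration
#'
#' The model's scalar output: the steady-state (or, for sustained
#' oscillations, tail-time-averaged) nuclear NFkB concentration after
#' applying zero or more drugs at the start of the simulation.
#'
#' @param model a `pathway_model` (drug-free baseline).
#' @param doses named numeric vector of doses in uM; names must match ids
#'   of `drugs`. May be empty / NULL for the control output.
#' @param drugs list of `drug_spec` objects, e.g. [default_drugs()].
#' @param ... passed to [steady_state()].
#' @return Nuclear NFkB concentration (uM).
#' @export
nuclear_nfkb_output <- function(model, doses = NULL, drugs = default_drugs(),
                                ...) {
  m <- model
  if (!is.null(doses) && length(doses)) {
    if (is.null(names(doses)) || any(!nzchar(names(doses))))
      stop("doses must be a named vector of drug ids")
    if (any(doses < 0)) stop("doses must be non-negative")
    for (id in names(doses)) {
      spec <- drugs[[id]]
      if (is.null(spec)) stop("unknown drug id: ", id)
      spec$dose <- doses[[id]]
      m <- apply_drug(m, spec)
    }
  }
  ss <- steady_state(m, ...)
  unname(ss$state[["NFkBn"]])
}
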