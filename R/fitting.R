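#' Time-course dataset container
#'
#' Cytoplasmic IkBa observed at 0, 5, 10, 15, 20, 30 min and nuclear NFkB at
#' 0, 10, 20, 30, 60, 120 min (the two assays were sampled on different
#' grids; the fit evaluates the model on the union grid and indexes into
#' it). Values are on the model's concentration scale (uM).
#'
#' @param ikb_times,ikb_values cytoplasmic IkBa grid (min) and values (uM).
#' @param nfkb_times,nfkb_values nuclear NFkB grid (min) and values (uM).
#' @param replicates optional data.frame of individual replicates
#'   (`observable`, `time_min`, `value`, `replicate`).
#' @param provenance free-text provenance tag (e.g. `synthetic(seed=1,cv=0.1)`).
#' @return A `timecourse_dataset`.
#' @export
timecourse_dataset <- function(ikb_times, ikb_values, nfkb_times,
                               nfkb_values, replicates = NULL,
                               provenance = "unspecified") {
  stopifnot(length(ikb_times) == length(ikb_values),
            length(nfkb_times) == length(nfkb_values))
  if (any(c(ikb_values, nfkb_values) < 0))
    stop("observed concentrations must be non-negative")
  if (is.null(replicates))
    replicates <- data.frame(observable = character(0),
                             time_min = numeric(0), value = numeric(0),
                             replicate = integer(0))
  structure(list(ikb_times = ikb_times, ikb_values = ikb_values,
                 nfkb_times = nfkb_times, nfkb_values = nfkb_values,
                 replicates = replicates, provenance = provenance),
            class = "timecourse_dataset")
}

#' Scale-free weights for the two-observable cost
#'
#' Each observable's squared-error sum is divided by that observable's sum
#' of squared observations, so the IkBa and NFkB terms contribute at the
#' same (relative) scale regardless of their absolute magnitudes.
#'
#' @param dataset a `timecourse_dataset`.
#' @return c(w_ikb, w_nfkb).
#' @export
cost_weights <- function(dataset) {
  c(w_ikb = 1 / sum(dataset$ikb_values^2),
    w_nfkb = 1 / sum(dataset$nfkb_values^2))
}

#' Weighted squared-error cost of a free-parameter vector
#'
#' `w1 * sum_t (IkB_model - IkB_data)^2 + w2 * sum_t (NFkB_model -
#' NFkB_data)^2`, with the model integrated once over the union of the two
#' time grids. An integration failure evaluates to the penalty `1e6`.
#'
#' @param free_params named (or free-parameter-ordered) numeric vector of
#'   the model's free rate constants.
#' @param dataset a `timecourse_dataset`.
#' @param model a `pathway_model`.
#' @param weights optional c(w_ikb, w_nfkb); default [cost_weights()].
#' @param penalty value returned when integration fails.
#' @return Scalar cost.
#' @export
fit_cost <- function(free_params, dataset, model, weights = NULL,
                     penalty = 1e6) {
  if (is.null(weights)) weights <- cost_weights(dataset)
  if (is.null(names(free_params)))
    names(free_params) <- free_parameters(model)
  grid <- sort(unique(c(dataset$ikb_times, dataset$nfkb_times)))
  tc <- tryCatch(
    integrate_model(model, times = grid, params = free_params,
                    rtol = 1e-8, atol = 1e-10),
    error = function(e) NULL)
  if (is.null(tc)) return(penalty)
  ikb_model  <- observable_ikb(tc)[match(dataset$ikb_times, grid)]
  nfkb_model <- species_trace(tc, "NFkBn")[match(dataset$nfkb_times, grid)]
  unname(weights[1] * sum((ikb_model - dataset$ikb_values)^2) +
         weights[2] * sum((nfkb_model - dataset$nfkb_values)^2))
}

# The western-blot IkBa observable: total cytoplasmic native IkBa (free and
# NFkB-bound; the antibody does not distinguish binding state, and
# phospho-IkBa is short-lived).
observable_ikb <- function(tc) {
  tc$states[, "IkB"] + tc$states[, "IkB_NFkB"]
}

#' Hooke-Jeeves pattern search
#'
#' Classic derivative-free pattern search on a box: exploratory coordinate
#' probes of the current step size around the base point; on improvement, an
#' accelerated pattern move doubles down along the improving direction; on
#' failure the step shrinks. Probes are clipped to the bounds. Stops when
#' the step falls below `tol`, the evaluation budget is exhausted, or the
#' objective reaches `target`.
#'
#' @param objective function of a numeric vector.
#' @param x0 start point (within bounds).
#' @param lower,upper bounds (scalars or vectors).
#' @param step0 initial step size, in box units.
#' @param shrink step shrink factor in (0, 1).
#' @param tol step-size stopping tolerance.
#' @param max_evals evaluation budget.
#' @param target early-stop objective value (default -Inf: disabled).
#' @return list with `x`, `f`, `evals`, `converged` (step < tol reached),
#'   and `trace` (best objective after each completed sweep).
#' @export
hooke_jeeves <- function(objective, x0, lower = 0, upper = 1, step0 = 0.1,
                         shrink = 0.5, tol = 1e-6, max_evals = 2e5,
                         target = -Inf) {
  stopifnot(shrink > 0, shrink < 1, step0 > 0)
  n <- length(x0)
  lo <- rep_len(lower, n)
  hi <- rep_len(upper, n)
  clip <- function(x) pmin(pmax(x, lo), hi)
  x0 <- clip(x0)
  evals <- 0L
  feval <- function(x) {
    evals <<- evals + 1L
    objective(x)
  }
  explore <- function(base, fbase, step) {
    x <- base
    fx <- fbase
    for (i in seq_len(n)) {
      for (dir in c(1, -1)) {
        cand <- x
        cand[i] <- min(max(cand[i] + dir * step, lo[i]), hi[i])
        if (cand[i] == x[i]) next
        fc <- feval(cand)
        if (fc < fx) {
          x <- cand
          fx <- fc
          break
        }
        if (evals >= max_evals) return(list(x = x, f = fx))
      }
      if (evals >= max_evals) break
    }
    list(x = x, f = fx)
  }
  base <- x0
  fbase <- feval(base)
  trace <- fbase
  step <- step0
  converged <- FALSE
  while (evals < max_evals && fbase > target) {
    ex <- explore(base, fbase, step)
    if (ex$f < fbase) {
      # pattern move: extrapolate along the successful direction
      repeat {
        pattern <- clip(ex$x + (ex$x - base))
        base <- ex$x
        fbase <- ex$f
        if (evals >= max_evals || fbase <= target) break
        fp <- feval(pattern)
        ex2 <- if (fp < fbase) explore(pattern, fp, step)
               else list(x = pattern, f = fp)
        if (ex2$f < fbase) {
          ex <- ex2
        } else break
      }
    } else {
      step <- step * shrink
      if (step < tol) {
        converged <- TRUE
        break
      }
    }
    trace <- c(trace, fbase)
  }
  list(x = base, f = fbase, evals = evals,
       converged = converged || fbase <= target, trace = trace)
}

#' Multistart Hooke-Jeeves fit of the 21 free parameters
#'
#' Starts are drawn uniformly in the unit box (the estimation search space
#' for every free rate constant is [0, 1]); the 18 receptor and IKK-cascade
#' constants stay fixed. Each run minimizes [fit_cost()] by
#' [hooke_jeeves()], stopping early when the cost reaches `target_error`.
#' The reported estimate is the arithmetic mean of the per-run final
#' vectors (the per-run table is retained so the best single run can be
#' used instead).
#'
#' @param dataset a `timecourse_dataset`.
#' @param model a `pathway_model` supplying topology and fixed constants.
#' @param n_starts number of random starts.
#' @param seed RNG seed; run `i` uses seed + i - 1.
#' @param target_error early-stop cost (the study's desired square error is
#'   0.01).
#' @param max_evals evaluation budget per run.
#' @param step0,shrink,tol pattern-search hyperparameters.
#' @return A `fit_result`: `per_run` data.frame (one row per start:
#'   parameters, cost, evals, converged, seed), `averaged_params`,
#'   `averaged_cost` (mean of per-run final costs), `cost_of_average`
#'   (cost evaluated at the averaged vector), `best_params`, `best_cost`.
#' @export
multistart_fit <- function(dataset, model, n_starts = 20, seed = 1,
                           target_error = 0.01, max_evals = 2e5,
                           step0 = 0.1, shrink = 0.5, tol = 1e-6) {
  stopifnot(n_starts >= 1)
  free <- free_parameters(model)
  weights <- cost_weights(dataset)
  obj <- function(x) fit_cost(setNames(x, free), dataset, model, weights)
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    run_seed <- seed + i - 1L
    set.seed(run_seed)
    x0 <- stats::runif(length(free))
    hj <- hooke_jeeves(obj, x0, lower = 0, upper = 1, step0 = step0,
                       shrink = shrink, tol = tol, max_evals = max_evals,
                       target = target_error)
    runs[[i]] <- c(setNames(hj$x, free),
                   cost = hj$f, evals = hj$evals,
                   converged = as.numeric(hj$converged), seed = run_seed)
  }
  per_run <- as.data.frame(do.call(rbind, runs))
  if (all(per_run$cost >= 1e6)) stop("all fit runs failed integration")
  avg <- colMeans(per_run[free])
  best_i <- which.min(per_run$cost)
  structure(list(
    per_run = per_run,
    averaged_params = setNames(as.numeric(avg), free),
    averaged_cost = mean(per_run$cost),
    cost_of_average = obj(as.numeric(avg)),
    best_params = setNames(as.numeric(per_run[best_i, free]), free),
    best_cost = per_run$cost[best_i],
    seeds = per_run$seed), class = "fit_result")
}

#' Install a fit's free parameters into a model
#' @param model a `pathway_model`.
#' @param free_params named vector of free rate constants.
#' @export
with_free_parameters <- function(model, free_params) {
  stopifnot(all(names(free_params) %in% free_parameters(model)))
  model$parameters[names(free_params)] <- free_params
  model
}
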