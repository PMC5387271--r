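#' Calibration dataset
#'
#' Long-form experimental observations: one row per measured point, with the
#' measurement time, the observed variable name, the value, and an optional
#' positive weight (default 1).
#'
#' @param time Numeric vector of measurement times.
#' @param variable Character vector of observed variable names.
#' @param value Numeric vector of measured values.
#' @param weight Positive weights (recycled; default 1).
#' @return An object of class `"kp_dataset"` (a data frame).
#' @export
dataset <- function(time, variable, value, weight = 1) {
  kp_check(length(time) == length(variable) && length(time) == length(value),
           "time, variable and value must have equal length")
  kp_check(length(time) >= 1L, "dataset must contain at least one observation")
  weight <- rep_len(weight, length(time))
  kp_check(all(is.finite(weight)) && all(weight > 0), "weights must be positive")
  structure(data.frame(time = as.numeric(time), variable = as.character(variable),
                       value = as.numeric(value), weight = as.numeric(weight),
                       stringsAsFactors = FALSE),
            class = c("kp_dataset", "data.frame"))
}

#' Read a calibration dataset from a wide TSV
#'
#' The file uses the report dialect: a `Time` column followed by one column
#' per observed variable. Missing cells (`NA`) are dropped.
#'
#' @param path Path to the TSV file.
#' @return A [dataset()].
#' @export
read_dataset <- function(path) {
  kp_check(file.exists(path), sprintf("dataset file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE)
  kp_check(ncol(df) >= 2L && colnames(df)[1] == "Time",
           sprintf("dataset '%s' must have a leading 'Time' column plus variables", path))
  long <- do.call(rbind, lapply(colnames(df)[-1], function(v) {
    keep <- !is.na(df[[v]])
    data.frame(time = df$Time[keep], variable = v, value = df[[v]][keep],
               stringsAsFactors = FALSE)
  }))
  dataset(long$time, long$variable, long$value)
}

#' Parameter search space
#'
#' One row per estimated parameter: name, positive lower bound, upper bound,
#' and search scale (`"log10"` or `"linear"`). Parameters not listed stay at
#' their model values. Log-scaled parameters are searched in log space, the
#' usual choice for kinetic rate constants whose plausible range spans orders
#' of magnitude.
#'
#' @param name Character vector of parameter names (unique).
#' @param lower,upper Bounds, `0 < lower < upper`.
#' @param scale `"log10"` (default) or `"linear"`, recycled.
#' @return An object of class `"param_space"` (a data frame).
#' @export
param_space <- function(name, lower, upper, scale = "log10") {
  kp_check(!anyDuplicated(name), "parameter names must be unique")
  kp_check(length(lower) == length(name) && length(upper) == length(name),
           "name, lower and upper must have equal length")
  kp_check(all(lower > 0) && all(is.finite(upper)) && all(lower < upper),
           "bounds must satisfy 0 < lower < upper (finite)")
  scale <- rep_len(scale, length(name))
  kp_check(all(scale %in% c("linear", "log10")), "scale must be 'linear' or 'log10'")
  structure(data.frame(name = as.character(name), lower = as.numeric(lower),
                       upper = as.numeric(upper), scale = scale,
                       stringsAsFactors = FALSE),
            class = c("param_space", "data.frame"))
}

# search-scale transforms
to_search <- function(v, scale) if (scale == "log10") log10(v) else v
from_search <- function(v, scale) if (scale == "log10") 10^v else v

space_search_bounds <- function(space) {
  lo <- mapply(to_search, space$lower, space$scale)
  hi <- mapply(to_search, space$upper, space$scale)
  list(lower = stats::setNames(lo, space$name),
       upper = stats::setNames(hi, space$name))
}

# objective penalty returned when the simulator fails inside an estimation:
# finite (so the swarm keeps moving and routes around pathological regions)
# but far above any realistic sum of squares
OBJECTIVE_PENALTY <- 1e100

#' Weighted sum-of-squares objective
#'
#' Simulates the model deterministically at the union of the dataset times
#' (with the trial parameter values substituted) and returns
#' \eqn{\sum_i w_i (y_i - \hat y_i)^2}. With `sd` given, residuals are divided
#' by that measurement standard deviation first, which puts the objective on
#' the \eqn{-2\log L} scale (up to a constant) that the chi-square confidence
#' thresholds of [sampled_ple()] assume. A simulation failure yields a large
#' finite penalty with a warning rather than an error, so that an optimiser
#' evaluating a pathological parameter set can continue.
#'
#' @param model A `"reaction_model"`.
#' @param space A [param_space()]; `params` must lie within its bounds.
#' @param data A [dataset()]; variables must be model readouts.
#' @param params Named numeric vector of trial values for the estimated
#'   parameters.
#' @param sd Optional positive measurement standard deviation used to
#'   normalise residuals.
#' @param spec Simulator options (tolerances).
#' @return Non-negative scalar objective value.
#' @export
objective_sse <- function(model, space, data, params, sd = NULL,
                          spec = simulator_spec("ode")) {
  kp_check(all(space$name %in% names(params)),
           "params must provide a value for every estimated parameter")
  kp_check(all(data$variable %in% model$readouts),
           "dataset variables must be model readouts")
  for (i in seq_len(nrow(space))) {
    v <- params[[space$name[i]]]
    kp_check(v >= space$lower[i] && v <= space$upper[i],
             sprintf("parameter '%s' outside its bounds", space$name[i]))
  }
  for (nm in space$name) model <- set_quantity(model, nm, params[[nm]])
  times <- sort(unique(data$time))
  tc <- tryCatch(simulate_ode(model, times, spec),
                 kinpipe_simulation_error = function(e) {
                   warning(sprintf("simulation failed during objective evaluation (%s); penalty objective returned",
                                   conditionMessage(e)), call. = FALSE)
                   NULL
                 })
  if (is.null(tc)) return(OBJECTIVE_PENALTY)
  sim <- tc$values[match(data$time, tc$times) + (match(data$variable, tc$variable_names) - 1L) * length(tc$times)]
  res <- data$value - sim
  if (!is.null(sd)) {
    kp_check(is.numeric(sd) && sd > 0, "sd must be positive")
    res <- res / sd
  }
  sum(data$weight * res^2)
}

#' Build an objective closure for the optimiser
#'
#' Binds model, space and data into a function of a named parameter vector,
#' as consumed by [pso_minimise()] and [run_repeats()].
#'
#' @inheritParams objective_sse
#' @return `function(params) -> objective value`.
#' @export
make_objective <- function(model, space, data, sd = NULL,
                           spec = simulator_spec("ode")) {
  force(model); force(space); force(data); force(sd); force(spec)
  function(params) objective_sse(model, space, data, params, sd = sd, spec = spec)
}

#' Particle swarm settings
#'
#' Constriction-style defaults: inertia 0.729 with cognitive and social
#' coefficients 1.494, a standard well-studied configuration. Positions are
#' initialised uniformly in the (possibly log-transformed) search box and
#' velocities are clamped to half the box width per dimension.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param iterations Number of update iterations (>= 1).
#' @param inertia Inertia weight.
#' @param cognitive,social Acceleration coefficients.
#' @param seed Integer RNG seed.
#' @return An object of class `"pso_settings"`.
#' @export
pso_settings <- function(swarm_size = 20L, iterations = 80L, inertia = 0.729,
                         cognitive = 1.494, social = 1.494, seed = 1L) {
  kp_check(swarm_size >= 2L, "swarm_size must be at least 2")
  kp_check(iterations >= 1L, "iterations must be at least 1")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 seed = as.integer(seed)),
            class = "pso_settings")
}

#' Particle swarm minimisation with full evaluation tracing
#'
#' Global-best PSO over the search box defined by a [param_space()].
#' Log-scaled parameters are searched in log10 space. Positions leaving the
#' box are clamped to the bounds before evaluation. Every evaluated position
#' is recorded — `swarm_size * (iterations + 1)` records in total (the `+ 1`
#' is the initial swarm) — because the sub-optimal evaluations are the raw
#' material of the sampled profile likelihood. The same seed reproduces the
#' trace exactly.
#'
#' @param f Objective: `function(named params) -> value`.
#' @param space A [param_space()].
#' @param settings A [pso_settings()].
#' @param repeat_id Integer tag stored in every record.
#' @return List with `best` (one-row data frame: repeat_id, eval_index,
#'   objective, parameters) and `trace` (all records, same columns).
#' @export
pso_minimise <- function(f, space, settings = pso_settings(), repeat_id = 1L) {
  kp_check(inherits(space, "param_space"), "space must be a param_space")
  kp_check(inherits(settings, "pso_settings"), "settings must be pso_settings")
  b <- space_search_bounds(space)
  d <- nrow(space)
  width <- b$upper - b$lower
  vmax <- width / 2
  ns <- settings$swarm_size
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(settings$seed)

  natural <- function(x) {
    stats::setNames(vapply(seq_len(d), function(j) from_search(x[j], space$scale[j]),
                           numeric(1)), space$name)
  }
  X <- matrix(stats::runif(ns * d, rep(b$lower, each = ns), rep(b$upper, each = ns)),
              ns, d)
  V <- matrix(stats::runif(ns * d, rep(-vmax / 2, each = ns), rep(vmax / 2, each = ns)),
              ns, d)
  n_evals <- ns * (settings$iterations + 1L)
  trace_obj <- numeric(n_evals)
  trace_par <- matrix(NA_real_, n_evals, d, dimnames = list(NULL, space$name))
  ev <- 0L
  evaluate <- function(x) {
    p <- natural(x)
    ev <<- ev + 1L
    trace_par[ev, ] <<- p
    obj <- f(p)
    trace_obj[ev] <<- obj
    obj
  }
  pbest_x <- X
  pbest_f <- apply(X, 1, evaluate)
  gi <- which.min(pbest_f)
  gbest_x <- X[gi, ]
  for (it in seq_len(settings$iterations)) {
    for (i in seq_len(ns)) {
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      V[i, ] <- settings$inertia * V[i, ] +
        settings$cognitive * r1 * (pbest_x[i, ] - X[i, ]) +
        settings$social * r2 * (gbest_x - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      X[i, ] <- pmin(pmax(X[i, ] + V[i, ], b$lower), b$upper)
      fi <- evaluate(X[i, ])
      if (fi < pbest_f[i]) {
        pbest_f[i] <- fi
        pbest_x[i, ] <- X[i, ]
        if (fi < pbest_f[gi] || i == gi) {
          gi <- which.min(pbest_f)
          gbest_x <- pbest_x[gi, ]
        }
      }
    }
  }
  trace <- data.frame(repeat_id = repeat_id, eval_index = seq_len(n_evals),
                      objective = trace_obj, stringsAsFactors = FALSE)
  trace <- cbind(trace, as.data.frame(trace_par))
  best <- trace[which.min(trace$objective), , drop = FALSE]
  rownames(best) <- NULL
  list(best = best, trace = trace)
}

#' Fit sequence: the record of repeated estimations
#'
#' Bundles every objective evaluation from all repeats (`all_evals`), the
#' best record of each repeat (`best_per_repeat`) and the repeat count.
#' Construction re-derives `best_per_repeat` from the evaluations, enforcing
#' the invariant that each entry is the minimum of its repeat.
#'
#' @param all_evals Data frame with columns `repeat_id`, `eval_index`,
#'   `objective` and one column per estimated parameter.
#' @param failed_repeats Integer ids of repeats that failed (recorded, not
#'   included in the evaluations).
#' @return An object of class `"fit_sequence"`.
#' @export
fit_sequence <- function(all_evals, failed_repeats = integer()) {
  need <- c("repeat_id", "eval_index", "objective")
  kp_check(is.data.frame(all_evals) && all(need %in% colnames(all_evals)) &&
             nrow(all_evals) > 0L,
           "all_evals must be a non-empty data frame with repeat_id, eval_index, objective")
  kp_check(all(all_evals$objective >= 0), "objective values must be non-negative")
  all_evals <- all_evals[order(all_evals$repeat_id, all_evals$eval_index), ,
                         drop = FALSE]
  rownames(all_evals) <- NULL
  ids <- sort(unique(all_evals$repeat_id))
  best <- do.call(rbind, lapply(ids, function(i) {
    sub <- all_evals[all_evals$repeat_id == i, , drop = FALSE]
    sub[which.min(sub$objective), , drop = FALSE]
  }))
  rownames(best) <- NULL
  structure(list(all_evals = all_evals, best_per_repeat = best,
                 n_repeats = length(ids),
                 parameters = setdiff(colnames(all_evals), need),
                 failed_repeats = as.integer(failed_repeats)),
            class = "fit_sequence")
}

#' @export
print.fit_sequence <- function(x, ...) {
  cat(sprintf("Fit sequence: %d repeats, %d objective evaluations, %d parameters (%s)\n",
              x$n_repeats, nrow(x$all_evals), length(x$parameters),
              paste(x$parameters, collapse = ", ")))
  b <- x$best_per_repeat
  g <- b[which.min(b$objective), ]
  cat(sprintf("  global best objective: %.6g (repeat %d)\n", g$objective, g$repeat_id))
  if (length(x$failed_repeats))
    cat("  failed repeats:", paste(x$failed_repeats, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fit_sequence <- function(object, ...) {
  b <- object$best_per_repeat
  cat(sprintf("Fit sequence over %d repeats\n", object$n_repeats))
  cat("Distribution of per-repeat best objectives:\n")
  print(summary(b$objective))
  cat("Global best parameters:\n")
  print(coef(object))
  invisible(object)
}

#' Global best parameter estimates of a fit sequence
#'
#' @param object A `"fit_sequence"`.
#' @param ... Unused.
#' @return Named numeric vector of the parameters at the overall minimum
#'   objective.
#' @export
coef.fit_sequence <- function(object, ...) {
  b <- object$best_per_repeat
  g <- b[which.min(b$objective), , drop = FALSE]
  unlist(g[object$parameters])
}

#' Repeated independent estimations
#'
#' Runs `n_repeats` particle swarm optimisations, each with a seed derived
#' deterministically from `(master_seed, repeat_id)`, optionally on several
#' local worker processes. The result is identical whatever the worker count
#' or completion order: records are keyed and sorted by `(repeat_id,
#' eval_index)`. A repeat that errors is recorded as failed and excluded; at
#' least one repeat must succeed.
#'
#' @param f Objective closure (see [make_objective()]).
#' @param space A [param_space()].
#' @param settings A [pso_settings()] (its `seed` field is overridden per
#'   repeat).
#' @param n_repeats Number of independent estimations (>= 1).
#' @param master_seed Integer master seed.
#' @param workers Local worker processes (>= 1, forked).
#' @return A [fit_sequence()].
#' @export
run_repeats <- function(f, space, settings, n_repeats, master_seed, workers = 1L) {
  kp_check(n_repeats >= 1L, "n_repeats must be at least 1")
  kp_check(workers >= 1L, "workers must be at least 1")
  one <- function(i) {
    s <- settings
    s$seed <- derive_seed(master_seed, i)
    tryCatch(pso_minimise(f, space, s, repeat_id = i),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "kp_failed_repeat"))
  }
  res <- run_parallel(seq_len(n_repeats), one, workers)
  failed <- which(vapply(res, inherits, logical(1), "kp_failed_repeat"))
  ok <- setdiff(seq_len(n_repeats), failed)
  if (length(ok) == 0L) {
    kp_stop("all estimation repeats failed", "kinpipe_pipeline_error")
  }
  if (length(failed)) {
    warning(sprintf("%d of %d estimation repeats failed and were excluded",
                    length(failed), n_repeats), call. = FALSE)
  }
  traces <- do.call(rbind, lapply(res[ok], `[[`, "trace"))
  fit_sequence(traces, failed_repeats = failed)
}
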