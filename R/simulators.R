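#' Time course container
#'
#' One trajectory on a time grid: a numeric `times` vector (minutes) and a
#' `values` matrix with one row per time and one named column per reported
#' variable. Rows align 1:1 with times and no entries are missing.
#'
#' @param times Increasing numeric vector.
#' @param values Numeric matrix, `length(times)` rows, named columns.
#' @return An object of class `"time_course"`.
#' @export
time_course <- function(times, values) {
  check_times(times)
  values <- as.matrix(values)
  kp_check(nrow(values) == length(times),
           "values must have one row per time point")
  kp_check(!is.null(colnames(values)) && all(nzchar(colnames(values))),
           "values columns must be named")
  kp_check(!anyNA(values), "time course values must not contain missing entries")
  structure(list(times = as.numeric(times), values = values,
                 variable_names = colnames(values)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %d time points (t = %g..%g), variables: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  data.frame(Time = x$times, x$values, check.names = FALSE)
}

#' @export
plot.time_course <- function(x, variables = x$variable_names, ...) {
  graphics::matplot(x$times, x$values[, variables, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (min)", ylab = "amount", ...)
  graphics::legend("topright", legend = variables, lty = 1,
                   col = seq_along(variables), bty = "n")
  invisible(x)
}

#' Ensemble of repeated stochastic time courses
#'
#' @param members List of [time_course()] objects sharing one time grid and
#'   variable set.
#' @param seeds Integer vector of per-member simulation seeds.
#' @return An object of class `"ensemble"`.
#' @export
ensemble <- function(members, seeds) {
  kp_check(is.list(members) && length(members) >= 1L &&
             all(vapply(members, inherits, logical(1), "time_course")),
           "members must be a non-empty list of time_course objects")
  kp_check(length(seeds) == length(members),
           "one seed per ensemble member is required")
  t0 <- members[[1]]$times
  v0 <- members[[1]]$variable_names
  for (m in members) {
    kp_check(identical(m$times, t0) && identical(m$variable_names, v0),
             "all ensemble members must share the same time grid and variables")
  }
  structure(list(members = members, seeds = as.integer(seeds),
                 times = t0, variable_names = v0),
            class = "ensemble")
}

#' Simulator specification
#'
#' Uniform description of how to run a model: the native deterministic ODE
#' engine, the native exact stochastic engine, or an external program driven
#' through the report-file protocol.
#'
#' @param kind `"ode"`, `"ssa"` or `"external"`.
#' @param rtol,atol Positive solver tolerances (ODE engine). Defaults are
#'   tight (`1e-8`/`1e-10`) because kinetic models are routinely stiff; the
#'   integrator (`lsoda`) switches to an implicit method as needed.
#' @param command For `kind = "external"`: a shell command template containing
#'   a `{report}` placeholder (mandatory) and optionally `{seed}`. The
#'   external program receives the report file path, runs the model, and must
#'   write the results as a report file (see [read_report()]).
#' @return An object of class `"simulator_spec"`.
#' @export
simulator_spec <- function(kind = c("ode", "ssa", "external"),
                           rtol = 1e-8, atol = 1e-10, command = NULL) {
  kind <- match.arg(kind)
  kp_check(is.numeric(rtol) && rtol > 0 && is.numeric(atol) && atol > 0,
           "solver tolerances must be positive")
  if (kind == "external") {
    kp_check(is.character(command) && length(command) == 1L &&
               grepl("{report}", command, fixed = TRUE),
             "external simulator needs a command template containing {report}")
  }
  structure(list(kind = kind, rtol = rtol, atol = atol, command = command),
            class = "simulator_spec")
}

#' Deterministic ODE simulation
#'
#' Integrates the mass-action rate equations with `deSolve::lsoda` (automatic
#' stiff/non-stiff switching). Fixed species are held constant. If the grid
#' does not start at 0 the system is still integrated from t = 0, where the
#' initial amounts are defined. Identical inputs give identical output across
#' runs.
#'
#' @param model A `"reaction_model"`.
#' @param times Strictly increasing numeric vector, `times[1] >= 0`.
#' @param spec A [simulator_spec()] (tolerances are taken from it).
#' @return A [time_course()] over the model readouts.
#' @export
simulate_ode <- function(model, times, spec = simulator_spec("ode")) {
  kp_check(inherits(model, "reaction_model"), "model must be a reaction_model")
  check_times(times)
  S <- stoichiometry_matrix(model)
  k <- vapply(model$reactions, function(r) model$parameters[[r$rate]], numeric(1))
  reactant_idx <- lapply(model$reactions, function(r) match(r$reactants, model$species$name))
  y0 <- stats::setNames(model$species$initial, model$species$name)
  # flatten the network for the compiled RHS (see src/massaction.c)
  desc <- c(nrow(model$species), length(k), k, as.double(S),
            lengths(reactant_idx), unlist(reactant_idx) - 1)
  .Call("kp_set_model", as.double(desc), PACKAGE = "kinpipe")
  grid <- if (times[1] > 0) c(0, times) else times
  sol <- tryCatch(
    deSolve::lsoda(y0, grid, func = "kp_derivs", parms = NULL,
                   dllname = "kinpipe", initfunc = NULL,
                   rtol = spec$rtol, atol = spec$atol),
    warning = function(w) {
      kp_stop(sprintf("ODE integration failed: %s", conditionMessage(w)),
              "kinpipe_simulation_error", time = NA_real_)
    },
    error = function(e) {
      kp_stop(sprintf("ODE integration failed: %s", conditionMessage(e)),
              "kinpipe_simulation_error", time = NA_real_)
    })
  if (nrow(sol) < length(grid)) {
    kp_stop(sprintf("ODE integration stopped early at t = %g", sol[nrow(sol), 1]),
            "kinpipe_simulation_error", time = sol[nrow(sol), 1])
  }
  keep <- match(times, grid)
  vals <- sol[keep, model$readouts, drop = FALSE]
  rownames(vals) <- NULL
  time_course(times, vals)
}

#' Exact stochastic simulation (Gillespie SSA)
#'
#' Simulates the reaction network as a continuous-time Markov jump process
#' with the direct Gillespie method and samples the piecewise-constant state
#' onto the requested grid: each grid time receives the state immediately
#' preceding it (the state in effect just before that instant; at a grid time
#' coinciding with a jump, the pre-jump state). The same seed always
#' reproduces the same trajectory, bit for bit.
#'
#' @param model A `"reaction_model"` with integer initial amounts.
#' @param times Strictly increasing numeric vector, `times[1] >= 0`.
#' @param seed Integer RNG seed.
#' @return A [time_course()] over the model readouts (integer-valued states).
#' @export
simulate_ssa <- function(model, times, seed) {
  kp_check(inherits(model, "reaction_model"), "model must be a reaction_model")
  check_times(times)
  init <- model$species$initial
  kp_check(all(init == round(init)),
           "stochastic simulation requires integer initial amounts")
  kp_check(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
           "seed must be a single integer")
  S <- stoichiometry_matrix(model)
  k <- vapply(model$reactions, function(r) model$parameters[[r$rate]], numeric(1))
  reactant_idx <- lapply(model$reactions, function(r) match(r$reactants, model$species$name))
  nr <- length(k)
  state <- stats::setNames(init, model$species$name)
  vals <- matrix(NA_real_, length(times), nrow(model$species),
                 dimnames = list(NULL, model$species$name))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  t_cur <- 0
  g <- 1L
  if (times[1] == 0) { vals[1, ] <- state; g <- 2L }
  G <- length(times)
  while (g <= G) {
    a <- vapply(seq_len(nr), function(j) k[j] * prod(state[reactant_idx[[j]]]), numeric(1))
    a0 <- sum(a)
    if (a0 <= 0) { # absorbing: state holds forever
      vals[g:G, ] <- matrix(state, G - g + 1L, length(state), byrow = TRUE)
      break
    }
    t_next <- t_cur + stats::rexp(1, a0)
    while (g <= G && times[g] <= t_next) { # pre-jump state covers (t_cur, t_next]
      vals[g, ] <- state
      g <- g + 1L
    }
    j <- findInterval(stats::runif(1) * a0, cumsum(a)) + 1L
    state <- state + S[, j]
    t_cur <- t_next
  }
  time_course(times, vals[, model$readouts, drop = FALSE])
}

#' Run repeated stochastic simulations as an ensemble
#'
#' Per-member seeds are derived deterministically from the master seed, so the
#' ensemble is reproducible and each member independently re-runnable.
#'
#' @param model A `"reaction_model"` with integer initial amounts.
#' @param times Simulation grid.
#' @param n Number of repeats.
#' @param master_seed Integer master seed.
#' @param workers Number of local worker processes (forked).
#' @return An [ensemble()].
#' @export
simulate_ssa_ensemble <- function(model, times, n, master_seed, workers = 1L) {
  kp_check(n >= 1L, "n must be at least 1")
  seeds <- vapply(seq_len(n), function(i) derive_seed(master_seed, i), integer(1))
  runs <- run_parallel(seq_len(n), function(i) simulate_ssa(model, times, seeds[i]),
                       workers)
  ensemble(runs, seeds)
}

#' Run a model through an external simulator
#'
#' Implements the wrapper protocol for models coded in any language: the
#' command template is resolved by substituting the report file path for
#' `{report}` (and the seed for `{seed}`, which wrappers may ignore), the
#' command is executed through the shell, and the report file it writes is
#' parsed into a time course. A non-zero exit status raises an
#' external-simulator error carrying the captured output; a missing or
#' malformed report raises a report-format error.
#'
#' @param spec A [simulator_spec()] with `kind = "external"`.
#' @param report_path Path where the external program must write its report.
#' @param seed Integer seed substituted for `{seed}` (default 1).
#' @return A [time_course()] parsed from the report file.
#' @export
run_external <- function(spec, report_path, seed = 1L) {
  kp_check(inherits(spec, "simulator_spec") && spec$kind == "external",
           "spec must be an external simulator_spec")
  cmd <- gsub("{report}", report_path, spec$command, fixed = TRUE)
  cmd <- gsub("{seed}", as.character(as.integer(seed)), cmd, fixed = TRUE)
  out <- suppressWarnings(system2("/bin/sh", c("-c", shQuote(cmd)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    kp_stop(sprintf("external simulator exited with status %d:\n%s",
                    status, paste(out, collapse = "\n")),
            "kinpipe_external_error", status = status, output = out)
  }
  if (!file.exists(report_path)) {
    kp_stop(sprintf("external simulator did not write report file '%s'", report_path),
            "kinpipe_report_format_error")
  }
  read_report(report_path)
}

derive_seed <- function(master_seed, i) {
  # splittable integer hash: distinct, reproducible per (master, repeat) pair,
  # independent of worker scheduling; kept below 2^31 - 1
  as.integer((as.double(master_seed) * 48271 + as.double(i) * 16807 + 1) %% 2147483629)
}

run_parallel <- function(idx, fn, workers) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, fn, mc.cores = workers, mc.set.seed = FALSE)
  } else {
    lapply(idx, fn)
  }
}
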