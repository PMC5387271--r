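# Synthetic calibration data: the controlled inputs for estimation and
# identifiability experiments. Two named scenarios contrast a time grid rich
# enough to pin down all rate constants of the receptor model against a
# truncated early-time grid that leaves the slow recovery rate unconstrained.

#' Generate a synthetic calibration dataset
#'
#' Simulates the model deterministically at the supplied true parameter
#' values, adds i.i.d. Gaussian noise (standard deviation `noise_sd`) to the
#' readouts, clips at zero (amounts are non-negative), and optionally writes
#' the result as a wide experiment TSV (`Time` + one column per readout, the
#' report dialect) for consumption by the estimation pipeline. Generation is
#' seed-deterministic.
#'
#' @param model A `"reaction_model"`.
#' @param params Named vector of true values for (a subset of) the model
#'   parameters; others stay at their model values.
#' @param times Measurement times (non-empty, increasing).
#' @param noise_sd Gaussian noise standard deviation, >= 0.
#' @param seed Integer RNG seed.
#' @param readouts Which readouts to observe (default: all model readouts).
#' @param file Optional path; when given the wide TSV is written there.
#' @return A [dataset()] (long form), invisibly carrying the file path as
#'   attribute `"file"` when one was written.
#' @export
make_dataset <- function(model, params, times, noise_sd = 0, seed = 1L,
                         readouts = model$readouts, file = NULL) {
  kp_check(length(times) >= 1L, "times must be non-empty")
  kp_check(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be non-negative")
  kp_check(all(readouts %in% model$readouts),
           "readouts must be among the model readouts")
  for (nm in names(params)) model <- set_quantity(model, nm, params[[nm]])
  tc <- simulate_ode(model, times)
  vals <- tc$values[, readouts, drop = FALSE]
  if (noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
    vals <- vals + matrix(stats::rnorm(length(vals), sd = noise_sd),
                          nrow(vals), ncol(vals))
    vals[vals < 0] <- 0
  }
  if (!is.null(file)) {
    write_report(time_course(tc$times, vals), file)
  }
  out <- dataset(rep(tc$times, ncol(vals)),
                 rep(colnames(vals), each = nrow(vals)),
                 as.vector(vals))
  attr(out, "file") <- file
  invisible(out)
}

#' Calibration scenario time grids
#'
#' Two contrasting designs for the insulin-receptor model. The `"sufficient"`
#' grid has 11 points spanning 0–45 minutes, covering the fast
#' phosphorylation transient and the slow refractory recovery, enough to
#' identify all three rate constants. The `"insufficient"` grid keeps only
#' the first two points (0 and 1 minute), before the refractory state has
#' accumulated: the recovery rate is then practically non-identifiable and
#' its confidence interval runs into the search bound.
#'
#' @param scenario `"sufficient"` or `"insufficient"`.
#' @return Numeric vector of measurement times (minutes).
#' @export
calibration_times <- function(scenario = c("sufficient", "insufficient")) {
  scenario <- match.arg(scenario)
  full <- c(0, 1, 2, 5, 10, 15, 20, 25, 30, 40, 45)
  if (scenario == "sufficient") full else full[1:2]
}

#' Synthetic fit sequence from a quadratic objective bowl
#'
#' Generates estimation records whose objective is an exact quadratic bowl,
#' `best + sum_j curvature_j * (v_j - centre_j)^2`, with parameter values
#' drawn uniformly around each centre. The sampled profile-likelihood
#' interval then has the closed form half-width `sqrt(Delta / curvature)`
#' (attained in the dense-sampling limit), which makes the fixture an
#' analytic oracle for the PLE machinery; with two or more parameters the
#' independent draws also give vanishing parameter correlations.
#'
#' @param n_repeats Number of synthetic repeats (>= 1).
#' @param n_evals Number of records per repeat (>= 1).
#' @param centres Named numeric vector of bowl centres (parameter names).
#' @param curvatures Positive curvatures, recycled to `length(centres)`.
#' @param best Objective value at the bowl minimum (default 0).
#' @param span Sampling half-range per parameter, in units of
#'   `sqrt(1/curvature)` (default 4: comfortably beyond the 99% cut).
#' @param seed Integer RNG seed.
#' @return List with `fits` (a [fit_sequence()]) and `space` (a linear-scale
#'   [param_space()] covering the sampling box).
#' @export
make_fit_sequence <- function(n_repeats, n_evals, centres = c(p1 = 5),
                              curvatures = 1, best = 0, span = 4, seed = 1L) {
  kp_check(n_repeats >= 1L && n_evals >= 1L,
           "n_repeats and n_evals must be at least 1")
  kp_check(!is.null(names(centres)) && all(nzchar(names(centres))),
           "centres must be a named vector")
  curvatures <- rep_len(curvatures, length(centres))
  kp_check(all(curvatures > 0), "curvatures must be positive")
  half <- span / sqrt(curvatures)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- n_repeats * n_evals
  V <- vapply(seq_along(centres), function(j) {
    stats::runif(n, centres[j] - half[j], centres[j] + half[j])
  }, numeric(n))
  V <- matrix(V, nrow = n, dimnames = list(NULL, names(centres)))
  obj <- best + as.vector((sweep(V, 2, centres)^2) %*% curvatures)
  ev <- data.frame(repeat_id = rep(seq_len(n_repeats), each = n_evals),
                   eval_index = rep(seq_len(n_evals), n_repeats),
                   objective = obj)
  ev <- cbind(ev, as.data.frame(V))
  lower <- pmax(centres - half, .Machine$double.eps)
  list(fits = fit_sequence(ev),
       space = param_space(names(centres), lower, centres + half,
                           scale = "linear"),
       centres = centres, curvatures = curvatures, best = best)
}
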