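#' Generate scan values
#'
#' Builds the value grid for a parameter scan. Three scales are supported:
#' `"linear"` (equally spaced), `"log10"` (equal steps in log space), and
#' `"percent"`, where `min`/`max` are percentages of a reference value —
#' the natural frame for simulated knockdown or overexpression (e.g. 0–200%
#' of the estimated level). Endpoints are always included; duplicate values
#' after generation are removed with a warning.
#'
#' @param min,max Range endpoints (on the chosen scale's input frame).
#' @param count Number of values (>= 2).
#' @param scale `"linear"`, `"log10"` or `"percent"`.
#' @param ref Reference value, required for `scale = "percent"`.
#' @return Numeric vector of scan values on the natural parameter scale.
#' @export
#' @examples
#' scan_values(1, 100, 3, scale = "log10") # 1, 10, 100
scan_values <- function(min, max, count, scale = c("linear", "log10", "percent"),
                        ref = NULL) {
  scale <- match.arg(scale)
  kp_check(count >= 2L, "a scan range needs at least 2 values")
  kp_check(is.finite(min) && is.finite(max) && min < max,
           "scan range must satisfy min < max")
  v <- switch(scale,
    linear = seq(min, max, length.out = count),
    log10 = {
      kp_check(min > 0, "log10 scan range requires min > 0")
      10^seq(log10(min), log10(max), length.out = count)
    },
    percent = {
      kp_check(!is.null(ref) && is.finite(ref),
               "percent scale requires a reference value")
      ref * seq(min, max, length.out = count) / 100
    })
  if (anyDuplicated(v)) {
    warning("duplicate scan values removed", call. = FALSE)
    v <- unique(v)
  }
  v
}

#' Single-parameter scan
#'
#' Simulates the model once per scan value of one parameter (or one species
#' initial amount), leaving the input model untouched. A simulation failure
#' at a value is recorded as missing with a warning and the scan continues.
#'
#' @param model A `"reaction_model"`.
#' @param parameter Name of a kinetic parameter or species.
#' @param values Scan values (see [scan_values()]).
#' @param times Simulation grid.
#' @param spec Simulator options.
#' @return An object of class `"scan_1d"`: scan `values`, the list of
#'   `trajectories` (`NULL` where a simulation failed) and a long-form
#'   data frame `table` with columns scan_value, time, variable, amount.
#' @export
scan_1d <- function(model, parameter, values, times,
                    spec = simulator_spec("ode")) {
  kp_check(length(values) >= 1L, "at least one scan value is required")
  get_quantity(model, parameter) # existence check
  trajectories <- vector("list", length(values))
  for (i in seq_along(values)) {
    trajectories[i] <- list(tryCatch(
      simulate_ode(set_quantity(model, parameter, values[i]), times, spec),
      kinpipe_error = function(e) {
        warning(sprintf("scan value %s = %g failed (%s); recorded as missing",
                        parameter, values[i], conditionMessage(e)), call. = FALSE)
        NULL
      }))
  }
  ok <- !vapply(trajectories, is.null, logical(1))
  table <- do.call(rbind, lapply(which(ok), function(i) {
    tc <- trajectories[[i]]
    data.frame(scan_value = values[i],
               time = rep(tc$times, length(tc$variable_names)),
               variable = rep(tc$variable_names, each = length(tc$times)),
               amount = as.vector(tc$values), stringsAsFactors = FALSE)
  }))
  structure(list(parameter = parameter, values = values,
                 trajectories = trajectories, table = table),
            class = "scan_1d")
}

#' Per-time-point envelope of a 1-D scan
#'
#' For each time point and variable, the min, max and median amount across
#' the scan values — the band plotted when a parameter is swept across its
#' confidence interval.
#'
#' @param x A `"scan_1d"`.
#' @return Data frame: time, variable, min, median, max.
#' @export
scan_envelope <- function(x) {
  kp_check(inherits(x, "scan_1d"), "x must be a scan_1d")
  kp_check(!is.null(x$table) && nrow(x$table) > 0, "scan produced no trajectories")
  agg <- stats::aggregate(amount ~ time + variable, data = x$table,
                          FUN = function(a) c(min = min(a), median = stats::median(a),
                                              max = max(a)))
  out <- data.frame(time = agg$time, variable = agg$variable,
                    min = agg$amount[, "min"], median = agg$amount[, "median"],
                    max = agg$amount[, "max"], stringsAsFactors = FALSE)
  out[order(out$variable, out$time), , drop = FALSE]
}

#' @export
print.scan_1d <- function(x, ...) {
  ok <- sum(!vapply(x$trajectories, is.null, logical(1)))
  cat(sprintf("1-D scan of '%s': %d values (%g..%g), %d simulations succeeded\n",
              x$parameter, length(x$values), min(x$values), max(x$values), ok))
  invisible(x)
}

#' Plot a 1-D scan as a trajectory band
#'
#' @param x A `"scan_1d"`.
#' @param variable Variable to draw (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scan_1d <- function(x, variable = NULL, ...) {
  env <- scan_envelope(x)
  variable <- variable %||% env$variable[1]
  s <- env[env$variable == variable, ]
  graphics::plot(s$time, s$median, type = "n", ylim = range(s$min, s$max),
                 xlab = "time (min)", ylab = variable, ...)
  graphics::polygon(c(s$time, rev(s$time)), c(s$min, rev(s$max)),
                    col = "lightsteelblue", border = NA)
  graphics::lines(s$time, s$median, lwd = 2, col = "navy")
  invisible(x)
}

#' Double-parameter scan
#'
#' Simulates the full Cartesian grid of two scanned quantities (kinetic
#' parameters or species initial amounts, e.g. the insulin input level
#' against the receptor level) and extracts per-time-point readout matrices
#' at the requested report times — the format of per-time heatmaps.
#'
#' @param model A `"reaction_model"`.
#' @param p1,p2 Names of the two scanned quantities (distinct).
#' @param values1,values2 Scan value vectors.
#' @param times Simulation grid.
#' @param report_times Times at which matrices are extracted; must be a
#'   subset of `times`.
#' @param spec Simulator options.
#' @return An object of class `"scan_2d"`: the grids, a 4-d array `amounts`
#'   indexed (value1, value2, time, variable), the report times, and a
#'   long-form `table`.
#' @export
scan_2d <- function(model, p1, values1, p2, values2, times,
                    report_times = times, spec = simulator_spec("ode")) {
  kp_check(p1 != p2, "the two scanned quantities must be distinct")
  get_quantity(model, p1); get_quantity(model, p2)
  kp_check(all(report_times %in% times),
           "report_times must be a subset of the simulation grid")
  vars <- model$readouts
  A <- array(NA_real_,
             dim = c(length(values1), length(values2), length(times), length(vars)),
             dimnames = list(NULL, NULL, NULL, vars))
  for (i in seq_along(values1)) {
    for (j in seq_along(values2)) {
      m <- set_quantity(set_quantity(model, p1, values1[i]), p2, values2[j])
      tc <- tryCatch(simulate_ode(m, times, spec),
                     kinpipe_error = function(e) {
                       warning(sprintf("grid cell (%g, %g) failed (%s); recorded as missing",
                                       values1[i], values2[j], conditionMessage(e)),
                               call. = FALSE)
                       NULL
                     })
      if (!is.null(tc)) A[i, j, , ] <- tc$values[, vars]
    }
  }
  grid <- expand.grid(v1 = values1, v2 = values2, time = times,
                      variable = vars, stringsAsFactors = FALSE)
  table <- data.frame(p1 = grid$v1, p2 = grid$v2, time = grid$time,
                      variable = grid$variable, amount = as.vector(A),
                      stringsAsFactors = FALSE)
  colnames(table)[1:2] <- c(p1, p2)
  structure(list(p1 = p1, p2 = p2, values1 = values1, values2 = values2,
                 times = times, report_times = report_times,
                 variables = vars, amounts = A, table = table),
            class = "scan_2d")
}

#' Extract one per-time-point matrix from a 2-D scan
#'
#' @param x A `"scan_2d"`.
#' @param time One of the scan's report times.
#' @param variable One of the model readouts.
#' @return Numeric matrix, `length(values1)` x `length(values2)`, with the
#'   scan values as dimnames.
#' @export
scan_matrix <- function(x, time, variable) {
  kp_check(inherits(x, "scan_2d"), "x must be a scan_2d")
  kp_check(time %in% x$report_times, "time must be one of the report times")
  kp_check(variable %in% x$variables, "unknown readout variable")
  M <- x$amounts[, , match(time, x$times), variable]
  M <- matrix(M, length(x$values1), length(x$values2),
              dimnames = list(format(x$values1, trim = TRUE),
                              format(x$values2, trim = TRUE)))
  M
}

#' @export
print.scan_2d <- function(x, ...) {
  cat(sprintf("2-D scan of '%s' (%d values) x '%s' (%d values), report times: %s\n",
              x$p1, length(x$values1), x$p2, length(x$values2),
              paste(x$report_times, collapse = ", ")))
  invisible(x)
}

#' Plot per-time-point heatmaps of a 2-D scan
#'
#' @param x A `"scan_2d"`.
#' @param variable Readout to draw (default: first).
#' @param times Report times to draw (default: all).
#' @param ... Passed to [graphics::image()].
#' @export
plot.scan_2d <- function(x, variable = x$variables[1], times = x$report_times, ...) {
  old <- graphics::par(mfrow = c(1, length(times)))
  on.exit(graphics::par(old))
  for (tt in times) {
    graphics::image(x$values1, x$values2, scan_matrix(x, tt, variable),
                    xlab = x$p1, ylab = x$p2,
                    main = sprintf("%s, t = %g min", variable, tt), ...)
  }
  invisible(x)
}
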