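#' Objective-offset threshold for a confidence level
#'
#' Likelihood-ratio confidence regions for an objective on the \eqn{-2\log L}
#' scale are delimited by the chi-square quantile: a parameter set belongs to
#' the region at level \eqn{\alpha} when its objective is within
#' \eqn{\Delta = \chi^2_{df}(\alpha)} of the global best. `df = 1` gives
#' pointwise (per-parameter) intervals; setting `df` to the number of
#' estimated parameters gives simultaneous regions.
#'
#' @param level Confidence level in (0, 1).
#' @param df Degrees of freedom (default 1, pointwise).
#' @return The non-negative offset \eqn{\Delta}.
#' @export
#' @examples
#' cl_threshold(0.95) # 3.8415
cl_threshold <- function(level, df = 1) {
  kp_check(is.numeric(level) && length(level) == 1L && level > 0 && level < 1,
           "level must lie strictly between 0 and 1")
  stats::qchisq(level, df = df)
}

#' Classify practical identifiability from a confidence interval
#'
#' A parameter is practically non-identifiable on a side when its confidence
#' interval reaches the search bound there: the data cannot constrain it in
#' that direction. The comparison is made on the parameter's search scale
#' (log10 for log-scaled parameters), with a tolerance expressed as a
#' fraction of the search-box width.
#'
#' @param ci Numeric length-2 interval (natural scale).
#' @param lower,upper Search bounds (natural scale).
#' @param scale `"linear"` or `"log10"`.
#' @param tol Relative tolerance (fraction of the search-scale box width).
#' @return One of `"identifiable"`, `"non_identifiable_left"`,
#'   `"non_identifiable_right"`, `"non_identifiable_both"`.
#' @export
classify_identifiability <- function(ci, lower, upper, scale = "linear",
                                     tol = 1e-3) {
  kp_check(length(ci) == 2L && ci[1] <= ci[2], "ci must be an interval")
  lo_s <- to_search(lower, scale); hi_s <- to_search(upper, scale)
  ci_s <- to_search(ci, scale)
  w <- hi_s - lo_s
  left <- (ci_s[1] - lo_s) <= tol * w
  right <- (hi_s - ci_s[2]) <= tol * w
  if (left && right) "non_identifiable_both"
  else if (left) "non_identifiable_left"
  else if (right) "non_identifiable_right"
  else "identifiable"
}

#' Sampled profile likelihood from a fit sequence
#'
#' Approximates each estimated parameter's profile likelihood by projecting
#' every recorded objective evaluation — not only the per-repeat best fits —
#' onto (parameter value, objective) pairs. The confidence interval at level
#' \eqn{\alpha} is the \[min, max\] of the values whose objective lies within
#' [cl_threshold()]`(level, df)` of the global best; no interpolation or
#' re-optimisation is performed. Each interval is then classified for
#' practical identifiability against the search bounds (the flag reported per
#' parameter is the one at the 95% level when present, otherwise at the
#' highest level).
#'
#' @param fits A [fit_sequence()].
#' @param space The [param_space()] the fits were generated under.
#' @param levels Increasing confidence levels in (0, 1).
#' @param df Degrees of freedom for the thresholds (see [cl_threshold()]).
#' @param tol Identifiability tolerance (see [classify_identifiability()]).
#' @return An object of class `"ple_result"` with a `table` data frame
#'   (parameter, level, threshold, lower, upper, n_qualifying, flag), the
#'   global `best` record, per-parameter projections in `samples`, and a
#'   per-parameter `flags` vector.
#' @export
sampled_ple <- function(fits, space, levels = c(0.66, 0.95, 0.99), df = 1,
                        tol = 1e-3) {
  kp_check(inherits(fits, "fit_sequence"), "fits must be a fit_sequence")
  kp_check(inherits(space, "param_space"), "space must be a param_space")
  kp_check(all(diff(levels) > 0), "levels must be strictly increasing")
  missing <- setdiff(space$name, fits$parameters)
  kp_check(length(missing) == 0L,
           sprintf("parameters absent from the fit records: %s",
                   paste(missing, collapse = ", ")))
  ev <- fits$all_evals
  best_obj <- min(ev$objective)
  thresholds <- stats::setNames(vapply(levels, cl_threshold, numeric(1), df = df),
                                as.character(levels))
  rows <- list()
  samples <- list()
  flags <- stats::setNames(character(nrow(space)), space$name)
  for (i in seq_len(nrow(space))) {
    p <- space$name[i]
    vals <- ev[[p]]
    ord <- order(vals)
    samples[[p]] <- data.frame(value = vals[ord], objective = ev$objective[ord])
    level_flags <- character(length(levels))
    for (li in seq_along(levels)) {
      qual <- vals[ev$objective <= best_obj + thresholds[li]]
      ci <- range(qual)
      level_flags[li] <- classify_identifiability(
        ci, space$lower[i], space$upper[i], space$scale[i], tol)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, level = levels[li], threshold = thresholds[[li]],
        lower = ci[1], upper = ci[2], n_qualifying = length(qual),
        flag = level_flags[li], stringsAsFactors = FALSE)
    }
    ref <- match(0.95, levels)
    flags[p] <- level_flags[if (is.na(ref)) length(levels) else ref]
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  best <- ev[which.min(ev$objective), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(table = table, best = best, best_objective = best_obj,
                 levels = levels, thresholds = thresholds, df = df,
                 samples = samples, flags = flags, space = space),
            class = "ple_result")
}

#' @export
print.ple_result <- function(x, digits = 4, ...) {
  cat(sprintf("Sampled profile likelihood: %d parameters, best objective %.6g\n",
              length(x$samples), x$best_objective))
  tab <- x$table
  tab$lower <- signif(tab$lower, digits)
  tab$upper <- signif(tab$upper, digits)
  tab$threshold <- signif(tab$threshold, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ple_result <- function(object, ...) {
  print(object, ...)
  ni <- names(object$flags)[object$flags != "identifiable"]
  if (length(ni)) {
    cat("Practically non-identifiable parameters:",
        paste(sprintf("%s (%s)", ni, object$flags[ni]), collapse = ", "), "\n")
  } else {
    cat("All parameters identifiable within the search bounds.\n")
  }
  invisible(object)
}

#' Plot a sampled profile likelihood
#'
#' One panel per parameter: the (value, objective) cloud with horizontal
#' lines at each confidence-level cutoff and vertical lines at the interval
#' endpoints for the highest level.
#'
#' @param x A `"ple_result"`.
#' @param parameters Which parameters to draw (default all).
#' @param ymax Upper objective limit for the y axis (default: best + 2x the
#'   largest threshold).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ple_result <- function(x, parameters = names(x$samples), ymax = NULL, ...) {
  np <- length(parameters)
  old <- graphics::par(mfrow = c(1, np))
  on.exit(graphics::par(old))
  ymax <- ymax %||% (x$best_objective + 2 * max(x$thresholds))
  for (p in parameters) {
    s <- x$samples[[p]]
    keep <- s$objective <= ymax
    sc <- x$space$scale[x$space$name == p]
    graphics::plot(s$value[keep], s$objective[keep], pch = 16, cex = 0.4,
                   col = "grey40", log = if (sc == "log10") "x" else "",
                   xlab = p, ylab = "objective", ...)
    for (li in seq_along(x$levels)) {
      graphics::abline(h = x$best_objective + x$thresholds[li], col = li + 1, lty = 2)
    }
    hi <- x$table[x$table$parameter == p & x$table$level == max(x$levels), ]
    graphics::abline(v = c(hi$lower, hi$upper), col = "grey60", lty = 3)
  }
  invisible(x)
}

#' Summary statistics of a stochastic ensemble
#'
#' Per variable and time point: the across-member mean, the sample standard
#' deviation (n - 1 denominator), and the t-based confidence interval of the
#' mean, `mean +/- t(1-(1-level)/2, n-1) * sd / sqrt(n)`. With a single
#' member only the mean is defined (sd and CI are `NA`).
#'
#' @param e An [ensemble()].
#' @param level Confidence level for the CI of the mean (default 0.95).
#' @return An object of class `"ensemble_summary"`: a data frame with columns
#'   time, variable, mean, sd, ci_low, ci_high, n.
#' @export
summarise_ensemble <- function(e, level = 0.95) {
  kp_check(inherits(e, "ensemble"), "e must be an ensemble")
  kp_check(level > 0 && level < 1, "level must lie in (0, 1)")
  n <- length(e$members)
  tcrit <- if (n >= 2) stats::qt(1 - (1 - level) / 2, df = n - 1) else NA_real_
  rows <- list()
  for (v in e$variable_names) {
    vm <- vapply(e$members, function(m) m$values[, v], numeric(length(e$times)))
    vm <- matrix(vm, nrow = length(e$times)) # guard length-1 grids
    mu <- rowMeans(vm)
    sdv <- if (n >= 2) apply(vm, 1, stats::sd) else rep(NA_real_, length(mu))
    half <- tcrit * sdv / sqrt(n)
    rows[[v]] <- data.frame(time = e$times, variable = v, mean = mu, sd = sdv,
                            ci_low = mu - half, ci_high = mu + half, n = n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ensemble_summary", "data.frame"),
            level = level)
}

#' Plot an ensemble summary
#'
#' Mean trajectory with the confidence band of the mean and the +/- 1 SD
#' band, one panel per variable.
#'
#' @param x An `"ensemble_summary"`.
#' @param variables Which variables to draw (default all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ensemble_summary <- function(x, variables = unique(x$variable), ...) {
  np <- length(variables)
  old <- graphics::par(mfrow = c(1, np))
  on.exit(graphics::par(old))
  for (v in variables) {
    s <- x[x$variable == v, ]
    ylim <- range(s$mean - s$sd, s$mean + s$sd, na.rm = TRUE)
    graphics::plot(s$time, s$mean, type = "n", ylim = ylim,
                   xlab = "time (min)", ylab = v, ...)
    graphics::polygon(c(s$time, rev(s$time)),
                      c(s$mean - s$sd, rev(s$mean + s$sd)),
                      col = "lightblue", border = NA)
    graphics::polygon(c(s$time, rev(s$time)),
                      c(s$ci_low, rev(s$ci_high)),
                      col = "cyan3", border = NA)
    graphics::lines(s$time, s$mean, lwd = 2)
  }
  invisible(x)
}

#' Parameter correlations from a fit sequence
#'
#' Pearson correlation matrices between estimated parameters, computed twice:
#' over the per-repeat best fits, and over all recorded evaluations whose
#' objective lies below the best plus the level threshold (default 95%).
#' Correlations are computed on the search scale (log10 values for
#' log-scaled parameters). A parameter that is constant across the records
#' has undefined correlations, reported as `NA`.
#'
#' @param fits A [fit_sequence()].
#' @param space The [param_space()] (supplies the search scales).
#' @param level Confidence level for the below-threshold matrix.
#' @param df Degrees of freedom for the threshold.
#' @return List of class `"correlation_result"` with matrices `best_fits`
#'   and `below_threshold`, plus the record counts used.
#' @export
parameter_correlations <- function(fits, space, level = 0.95, df = 1) {
  kp_check(inherits(fits, "fit_sequence"), "fits must be a fit_sequence")
  pars <- space$name
  on_scale <- function(df_in) {
    m <- as.matrix(df_in[pars])
    for (i in seq_along(pars)) {
      if (space$scale[i] == "log10") m[, i] <- log10(m[, i])
    }
    m
  }
  corr <- function(m) {
    kp_check(nrow(m) >= 3L,
             "at least 3 qualifying records are required for a correlation matrix")
    const <- apply(m, 2, function(x) stats::sd(x) == 0)
    r <- suppressWarnings(stats::cor(m))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
    diag(r) <- ifelse(const, NA_real_, 1)
    r
  }
  ev <- fits$all_evals
  cut <- min(ev$objective) + cl_threshold(level, df)
  sub <- ev[ev$objective <= cut, , drop = FALSE]
  structure(list(best_fits = corr(on_scale(fits$best_per_repeat)),
                 below_threshold = corr(on_scale(sub)),
                 n_best = nrow(fits$best_per_repeat), n_below = nrow(sub),
                 level = level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  cat(sprintf("Parameter correlations (best fits, n = %d):\n", x$n_best))
  print(round(x$best_fits, digits))
  cat(sprintf("Below the %g%% threshold (n = %d):\n", 100 * x$level, x$n_below))
  print(round(x$below_threshold, digits))
  invisible(x)
}
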