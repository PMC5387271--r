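test_that("confidence-level thresholds match the closed-form chi-square(1) oracle", {
  # chi-square(1) is the square of a standard normal: Delta = qnorm((1+l)/2)^2
  for (l in c(0.5, 0.66, 0.95, 0.99)) {
    expect_equal(cl_threshold(l), chisq1_quantile_oracle(l), tolerance = 1e-9)
  }
  expect_equal(cl_threshold(0.95), 3.841459, tolerance = 1e-6)
  expect_equal(cl_threshold(0.99), 6.634897, tolerance = 1e-6)
  expect_lt(cl_threshold(1e-8), 1e-6) # vanishes at level -> 0
  expect_gt(cl_threshold(0.95, df = 3), cl_threshold(0.95, df = 1))
  expect_error(cl_threshold(1), class = "kinpipe_validation_error")
  expect_error(cl_threshold(0), class = "kinpipe_validation_error")
})

test_that("sampled PLE reproduces the hand-filtered example", {
  fits <- fits_from_pairs(c(10, 20, 30, 40, 50), c(1, 2, 4, 4.8, 6))
  space <- param_space("p", 1, 1000, scale = "linear")
  ple <- sampled_ple(fits, space, levels = c(0.95, 0.99))
  t95 <- ple$table[ple$table$level == 0.95, ]
  expect_equal(c(t95$lower, t95$upper), c(10, 40)) # cut at 1 + 3.8415 = 4.8415
  t99 <- ple$table[ple$table$level == 0.99, ]
  expect_equal(c(t99$lower, t99$upper), c(10, 50)) # cut at 7.6349, nests the 95%
})

test_that("a single record collapses every interval to a point", {
  fits <- fits_from_pairs(3, 0.5)
  ple <- sampled_ple(fits, param_space("p", 1, 10, scale = "linear"))
  expect_true(all(ple$table$lower == 3 & ple$table$upper == 3))
  expect_true(all(ple$table$flag == "identifiable"))
})

test_that("parameters absent from the records are rejected", {
  fits <- fits_from_pairs(1:5, rep(1, 5))
  expect_error(sampled_ple(fits, param_space("other", 1, 10, scale = "linear")),
               class = "kinpipe_validation_error")
})

test_that("identifiability classification follows the interval-vs-bounds rule", {
  expect_equal(classify_identifiability(c(0.2, 0.8), 0.01, 10), "identifiable")
  expect_equal(classify_identifiability(c(0.2, 10), 0.01, 10), "non_identifiable_right")
  expect_equal(classify_identifiability(c(0.01, 0.8), 0.01, 10), "non_identifiable_left")
  expect_equal(classify_identifiability(c(0.01, 10), 0.01, 10), "non_identifiable_both")
  # comparison happens on the search scale
  expect_equal(classify_identifiability(c(0.02, 9), 0.01, 10, scale = "log10"),
               "identifiable")
})

test_that("PLE intervals nest across levels and equal a brute-force filter", {
  set.seed(81)
  for (case in 1:5) {
    n <- sample(50:400, 1)
    vals <- runif(n, 0, 10)
    objs <- runif(n, 0, 12)
    fits <- fits_from_pairs(vals, objs)
    space <- param_space("p", 1e-3, 11, scale = "linear")
    levels <- c(0.66, 0.95, 0.99)
    ple <- sampled_ple(fits, space, levels = levels)
    best <- min(objs)
    prev <- NULL
    for (l in levels) {
      qual <- vals[objs <= best + qchisq(l, 1)] # brute-force oracle
      row <- ple$table[ple$table$level == l, ]
      expect_equal(row$lower, min(qual))
      expect_equal(row$upper, max(qual))
      expect_equal(row$n_qualifying, length(qual))
      if (!is.null(prev)) { # wider level contains the narrower one
        expect_lte(row$lower, prev$lower)
        expect_gte(row$upper, prev$upper)
      }
      prev <- row
    }
    # the best-fit value lies in every interval
    bv <- vals[which.min(objs)]
    expect_true(all(ple$table$lower <= bv & bv <= ple$table$upper))
  }
})

test_that("ensemble summaries match hand-computed statistics", {
  tc <- function(v) time_course(c(0, 1), matrix(v, 2, 1, dimnames = list(NULL, "X")))
  # identical members: zero spread
  e <- ensemble(list(tc(c(1, 5)), tc(c(1, 5)), tc(c(1, 5))), seeds = 1:3)
  s <- summarise_ensemble(e)
  expect_equal(s$sd, rep(0, 2))
  expect_equal(s$ci_low, s$mean)
  expect_equal(s$ci_high, s$mean)
  # two members with values 0 and 2: mean 1, sd sqrt(2) (n-1 denominator)
  e2 <- ensemble(list(tc(c(0, 0)), tc(c(2, 2))), seeds = 1:2)
  s2 <- summarise_ensemble(e2)
  expect_equal(s2$mean, rep(1, 2))
  expect_equal(s2$sd, rep(sqrt(2), 2))
  # t-based CI: mean +/- qt(0.975, 1) * sd / sqrt(2)
  half <- qt(0.975, 1) * sqrt(2) / sqrt(2)
  expect_equal(s2$ci_high - s2$mean, rep(half, 2))
  expect_error(summarise_ensemble(list()), class = "kinpipe_validation_error")
})

test_that("the ensemble CI of the mean covers the analytic mean at most time points", {
  m <- ir_receptor_model()
  tt <- seq(0, 10, by = 0.25)
  e <- simulate_ssa_ensemble(m, tt, n = 40, master_seed = 11)
  s <- summarise_ensemble(e, 0.95)
  truth <- linear_solution(m, tt)
  covered <- 0L; total <- 0L
  for (v in e$variable_names) {
    sv <- s[s$variable == v, ]
    tv <- truth$values[, v]
    covered <- covered + sum(sv$ci_low <= tv & tv <= sv$ci_high)
    total <- total + length(tv)
  }
  expect_gte(covered / total, 0.9)
})

test_that("parameter correlations detect exact dependence and independence", {
  n <- 1000
  set.seed(4)
  p1 <- runif(n, 1, 2)
  df <- data.frame(repeat_id = rep(1:5, each = n / 5),
                   eval_index = rep(seq_len(n / 5), 5), objective = runif(n),
                   p1 = p1, p2 = 2 * p1, p3 = runif(n, 1, 2))
  fits <- fit_sequence(df)
  space <- param_space(c("p1", "p2", "p3"), rep(0.1, 3), rep(10, 3),
                       scale = "linear")
  co <- parameter_correlations(fits, space, level = 0.95)
  expect_equal(co$below_threshold["p1", "p2"], 1.0, tolerance = 1e-12)
  expect_lt(abs(co$below_threshold["p1", "p3"]), 0.1)
  expect_true(isSymmetric(co$below_threshold))
  expect_equal(unname(diag(co$below_threshold)), rep(1, 3))
  expect_true(all(abs(co$below_threshold) <= 1))
})

test_that("a constant parameter has undefined (not zero) correlations", {
  df <- data.frame(repeat_id = 1:10, eval_index = 1L, objective = runif(10),
                   p1 = runif(10), p2 = 1)
  fits <- fit_sequence(df)
  space <- param_space(c("p1", "p2"), c(0.01, 0.01), c(10, 10), scale = "linear")
  co <- parameter_correlations(fits, space)
  expect_true(is.na(co$below_threshold["p1", "p2"]))
  expect_true(is.na(co$below_threshold["p2", "p2"]))
  expect_equal(co$below_threshold["p1", "p1"], 1)
})
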