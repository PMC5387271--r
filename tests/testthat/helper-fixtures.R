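# Shared fixtures: the receptor model at default truth, a standard search
# space, and small helpers used across test files.

ir_truth <- c(k1 = 0.5, k2 = 1.0, k3 = 0.1)

ir_space <- function() {
  param_space(c("k1", "k2", "k3"), rep(1e-3, 3), rep(100, 3), scale = "log10")
}

# noise-free calibration data over a named scenario, phosphorylated readout
ir_data <- function(scenario = "sufficient", noise_sd = 0, seed = 1L,
                    file = NULL) {
  make_dataset(ir_receptor_model(), ir_truth, calibration_times(scenario),
               noise_sd = noise_sd, seed = seed,
               readouts = "IR_beta_pY1164", file = file)
}

# hand-built fit sequence from explicit (value, objective) pairs, one repeat
fits_from_pairs <- function(values, objectives, param = "p") {
  df <- data.frame(repeat_id = 1L, eval_index = seq_along(values),
                   objective = objectives)
  df[[param]] <- values
  fit_sequence(df)
}

# independent closed form for the chi-square(1) quantile: if Z ~ N(0,1) then
# Z^2 ~ chi-square(1), so the quantile is qnorm((1 + level) / 2)^2
chisq1_quantile_oracle <- function(level) qnorm((1 + level) / 2)^2

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), .Machine$double.eps)),
            tol)
}
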