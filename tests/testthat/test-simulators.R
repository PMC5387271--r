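test_that("ODE engine matches the analytic oracle on the linear fixture", {
  m <- ir_receptor_model()
  tt <- seq(0, 10, by = 0.25)
  ode <- simulate_ode(m, tt)
  oracle <- linear_solution(m, tt)
  rel <- abs(ode$values - oracle$values) / pmax(abs(oracle$values), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("near-zero kinetics leave the state at its initial amounts", {
  m <- ir_receptor_model(k1 = 1e-14, k2 = 1e-14, k3 = 1e-14)
  tc <- simulate_ode(m, c(0, 5, 10))
  expect_equal(unname(tc$values[, "IR_beta"]), rep(16, 3), tolerance = 1e-9)
  expect_equal(unname(tc$values[, "IR_beta_pY1164"]), rep(0, 3), tolerance = 1e-9)
})

test_that("the ODE trajectory conserves total receptor", {
  tc <- simulate_ode(ir_receptor_model(), seq(0, 45, by = 0.5))
  expect_rel_equal(rowSums(tc$values), rep(16, length(tc$times)), 1e-7)
})

test_that("grid refinement does not change the solution on the coarse grid", {
  m <- ir_receptor_model()
  coarse <- seq(0, 10, by = 1)
  fine <- seq(0, 10, by = 0.1)
  a <- simulate_ode(m, coarse)
  b <- simulate_ode(m, fine)
  keep <- match(coarse, fine)
  expect_rel_equal(b$values[keep, ], a$values, 1e-6)
})

test_that("stochastic trajectories conserve total receptor exactly and repeat by seed", {
  m <- ir_receptor_model()
  tt <- seq(0, 10, by = 0.5)
  for (s in c(1L, 99L, 2024L)) {
    tc <- simulate_ssa(m, tt, seed = s)
    expect_true(all(rowSums(tc$values) == 16))
    expect_true(all(tc$values == round(tc$values)))
  }
  expect_identical(simulate_ssa(m, tt, seed = 7L), simulate_ssa(m, tt, seed = 7L))
})

test_that("stochastic simulation requires integer initial amounts", {
  m <- ir_receptor_model(ir0 = 15.5)
  expect_error(simulate_ssa(m, c(0, 1), seed = 1L),
               class = "kinpipe_validation_error")
})

test_that("the SSA mean agrees with the ODE solution for linear kinetics", {
  # for a linear network the jump-process mean obeys the rate equations
  m <- ir_receptor_model()
  n <- 300
  at2 <- vapply(seq_len(n), function(s) {
    simulate_ssa(m, c(0, 2), seed = s)$values[2, "IR_beta_pY1164"]
  }, numeric(1))
  truth <- linear_solution(m, c(0, 2))$values[2, "IR_beta_pY1164"]
  se <- sd(at2) / sqrt(n)
  expect_lt(abs(mean(at2) - truth), 3 * se)
})

test_that("ensemble members are reproducible and independent of worker count", {
  m <- ir_receptor_model()
  tt <- seq(0, 5, by = 0.5)
  e1 <- simulate_ssa_ensemble(m, tt, n = 6, master_seed = 5, workers = 1)
  e2 <- simulate_ssa_ensemble(m, tt, n = 6, master_seed = 5, workers = 3)
  expect_identical(e1$members, e2$members)
  expect_identical(e1$seeds, e2$seeds)
})

test_that("report files round-trip through write and read", {
  tc <- simulate_ode(ir_receptor_model(), seq(0, 10, by = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(tc, path)
  back <- read_report(path)
  expect_equal(back$times, tc$times)
  expect_equal(back$values, tc$values)
})

test_that("report parsing is header-driven, not positional", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Time\tB\tA", "0\t10\t1", "1\t20\t2"), path)
  tc <- read_report(path)
  expect_equal(unname(tc$values[, "A"]), c(1, 2))
  expect_equal(unname(tc$values[, "B"]), c(10, 20))
})

test_that("malformed report files raise format errors naming the problem", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Time\tA", p) # header only
  expect_error(read_report(p), class = "kinpipe_report_format_error")
  writeLines(c("Time\tA", "0\t1\t9"), p) # extra field
  expect_error(read_report(p), regexp = "line 2",
               class = "kinpipe_report_format_error")
  writeLines(c("Elapsed\tA", "0\t1"), p) # wrong leading column
  expect_error(read_report(p), class = "kinpipe_report_format_error")
})

test_that("the external wrapper protocol parses reports and surfaces failures", {
  # fixed three-row report written by a shell one-liner
  spec <- simulator_spec("external",
                         command = "printf 'Time\\tX\\n0\\t1\\n1\\t2\\n2\\t4\\n' > {report}")
  tc <- run_external(spec, withr::local_tempfile(fileext = ".tsv"), seed = 1)
  expect_equal(tc$times, c(0, 1, 2))
  expect_equal(unname(tc$values[, "X"]), c(1, 2, 4))

  failing <- simulator_spec("external", command = "echo boom >&2; false # {report}")
  expect_error(run_external(failing, withr::local_tempfile()),
               class = "kinpipe_external_error")

  silent <- simulator_spec("external", command = "true # {report}")
  expect_error(run_external(silent, withr::local_tempfile()),
               class = "kinpipe_report_format_error")
})

test_that("an external re-implementation of the receptor ODE agrees with the native engine", {
  # independent wrapper: plain deSolve with a hand-written RHS, no kinpipe
  wrapper <- withr::local_tempfile(fileext = ".R")
  writeLines(c(
    "args <- commandArgs(trailingOnly = TRUE)",
    "rhs <- function(t, y, p) {",
    "  v1 <- 0.5 * y[1] * 1; v2 <- 1.0 * y[2]; v3 <- 0.1 * y[3]",
    "  list(c(-v1 + v3, v1 - v2, v2 - v3))",
    "}",
    "tt <- seq(0, 10, by = 0.5)",
    "out <- deSolve::lsoda(c(IR_beta = 16, IR_beta_pY1164 = 0, IR_beta_refrac = 0),",
    "                      tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)",
    "df <- as.data.frame(out); colnames(df)[1] <- 'Time'",
    "write.table(format(df, digits = 17), args[1], sep = '\\t',",
    "            quote = FALSE, row.names = FALSE)"), wrapper)
  spec <- simulator_spec("external",
                         command = sprintf("Rscript %s {report} {seed}", wrapper))
  got <- run_external(spec, withr::local_tempfile(fileext = ".tsv"), seed = 3)
  ref <- simulate_ode(ir_receptor_model(), seq(0, 10, by = 0.5))
  expect_lt(max(abs(got$values[, ref$variable_names] - ref$values)), 1e-4)
})
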