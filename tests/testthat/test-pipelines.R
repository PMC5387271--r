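# End-to-end pipeline tests use deliberately small problem sizes (few repeats,
# small swarms) -- the statistical behaviour of each component is covered by
# its own unit tests.

model_path <- function() {
  system.file("extdata", "insulin_receptor.yaml", package = "kinpipe")
}

simulate_cfg <- function(dir, runs = 5, kind = "ssa", extra = list()) {
  cfg <- c(list(pipeline = "simulate", model = model_path(),
                output_dir = file.path(dir, "out"),
                simulator = list(kind = kind), runs = runs, master_seed = 42,
                times = list(from = 0, to = 5, by = 0.5)),
           extra)
  validate_config(cfg, base_dir = dir)
}

estim_cfg <- function(dir, runs = 4, workers = 1, master_seed = 7,
                      out = "out") {
  data_path <- file.path(dir, "calib.tsv")
  if (!file.exists(data_path)) {
    make_dataset(ir_receptor_model(), ir_truth, calibration_times("sufficient"),
                 noise_sd = 0, readouts = "IR_beta_pY1164", file = data_path)
  }
  validate_config(list(
    pipeline = "param_estim", model = model_path(),
    output_dir = file.path(dir, out), dataset = data_path,
    parameters = list(list(name = "k1", lower = 1e-3, upper = 100),
                      list(name = "k2", lower = 1e-3, upper = 100),
                      list(name = "k3", lower = 1e-3, upper = 100)),
    pso = list(swarm_size = 10, iterations = 15),
    runs = runs, master_seed = master_seed, workers = workers),
    base_dir = dir)
}

test_that("configuration validation injects defaults and rejects bad input", {
  cfg <- validate_config(list(pipeline = "simulate", model = "m.yaml",
                              output_dir = "out"), base_dir = "/base")
  expect_equal(cfg$workers, 1L)
  expect_equal(cfg$runs, 1L)
  expect_equal(cfg$level, 0.95)
  expect_true(cfg$generate_data && cfg$analyse_data && cfg$generate_report)
  expect_equal(cfg$model, "/base/m.yaml")
  expect_equal(cfg$simulator$kind, "ode")

  expect_error(validate_config(list(pipeline = "simulat", model = "m", output_dir = "o")),
               regexp = "simulate, single_param_scan, double_param_scan, param_estim")
  expect_error(validate_config(list(pipeline = "simulate", model = "m",
                                    output_dir = "o", swarm = 3)),
               regexp = "swarm", class = "kinpipe_config_error")
  expect_error(validate_config(list(pipeline = "simulate", model = "m",
                                    output_dir = "o", cluster = "sge")),
               class = "kinpipe_unsupported_feature_error")
  expect_error(validate_config(list(pipeline = "simulate", output_dir = "o")),
               regexp = "model")
})

test_that("configuration files round-trip through YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(pipeline = "simulate", model = "m.yaml",
                        output_dir = "results", runs = 3,
                        simulator = list(kind = "ssa")), path)
  cfg <- read_config(path)
  expect_equal(cfg$runs, 3L)
  expect_equal(cfg$simulator$kind, "ssa")
  expect_equal(cfg$output_dir, file.path(normalizePath(dir), "results"))
})

test_that("the stochastic simulate pipeline writes reports, statistics and report sources", {
  dir <- withr::local_tempdir()
  dirs <- run_pipeline(simulate_cfg(dir, runs = 5))
  raw <- list.files(dirs$raw, pattern = "^simulation_.*tsv$")
  expect_length(raw, 5)
  expect_true(file.exists(file.path(dirs$analysis, "ensemble_summary.tsv")))
  expect_true(file.exists(file.path(dirs$analysis, "ensemble.pdf")))
  expect_true(file.exists(file.path(dirs$report, "report.tex")))
  expect_true(file.exists(file.path(dirs$report, "report.md")))
  expect_true(file.exists(dirs$manifest))
  s <- utils::read.delim(file.path(dirs$analysis, "ensemble_summary.tsv"))
  expect_equal(unique(s$n), 5)
  expect_true(all(s$sd >= 0, na.rm = TRUE))
})

test_that("a deterministic simulate run collapses repeats to a single simulation", {
  dir <- withr::local_tempdir()
  expect_message(dirs <- run_pipeline(simulate_cfg(dir, runs = 10, kind = "ode")),
                 regexp = "single run")
  expect_length(list.files(dirs$raw, pattern = "tsv$"), 1)
  expect_true(file.exists(file.path(dirs$analysis, "timecourse.tsv")))
})

test_that("disabling generation re-analyses existing data without touching it", {
  dir <- withr::local_tempdir()
  cfg <- simulate_cfg(dir, runs = 4)
  dirs <- run_pipeline(cfg)
  raw_files <- list.files(dirs$raw, full.names = TRUE)
  before <- tools::md5sum(raw_files)
  first <- utils::read.delim(file.path(dirs$analysis, "ensemble_summary.tsv"))

  cfg$generate_data <- FALSE
  cfg$level <- 0.5 # tighter CI of the mean: analysis outputs must change
  run_pipeline(cfg)
  expect_identical(tools::md5sum(raw_files), before)
  second <- utils::read.delim(file.path(dirs$analysis, "ensemble_summary.tsv"))
  expect_true(all(second$ci_high - second$ci_low <= first$ci_high - first$ci_low + 1e-12))
  expect_false(isTRUE(all.equal(first$ci_high, second$ci_high)))
})

test_that("analysis without prior data names the missing files", {
  dir <- withr::local_tempdir()
  cfg <- simulate_cfg(dir)
  cfg$generate_data <- FALSE
  expect_error(run_pipeline(cfg), regexp = "manifest",
               class = "kinpipe_pipeline_error")
})

test_that("analysis refuses a mismatched output layout version", {
  dir <- withr::local_tempdir()
  cfg <- simulate_cfg(dir, runs = 2)
  dirs <- run_pipeline(cfg)
  m <- jsonlite::read_json(dirs$manifest)
  m$layout_version <- 99
  jsonlite::write_json(m, dirs$manifest, auto_unbox = TRUE)
  cfg$generate_data <- FALSE
  expect_error(run_pipeline(cfg), regexp = "layout version",
               class = "kinpipe_pipeline_error")
})

test_that("the estimation pipeline produces traces, intervals, correlations and reports", {
  dir <- withr::local_tempdir()
  dirs <- run_pipeline(estim_cfg(dir, runs = 4))
  expect_length(list.files(dirs$raw, pattern = "^estimation_.*tsv$"), 4)
  expect_true(file.exists(file.path(dirs$raw, "best_fits.tsv")))
  ci <- utils::read.delim(file.path(dirs$analysis, "ci_summary.tsv"))
  expect_equal(nrow(ci), 9) # 3 parameters x 3 levels
  expect_true(all(c("ple_k1.tsv", "ple_k2.tsv", "ple_k3.tsv",
                    "correlations_best.tsv", "correlations_cl95.tsv",
                    "best_fit.tsv") %in% list.files(dirs$analysis)))
  # fit sequence rebuilt from disk equals nothing lost: 4 repeats, full traces
  fits <- read_fit_sequence(dirs$raw)
  expect_equal(fits$n_repeats, 4)
  expect_equal(nrow(fits$all_evals), 4 * 10 * 16)
  best <- utils::read.delim(file.path(dirs$analysis, "best_fit.tsv"))
  expect_equal(best$parameter, c("k1", "k2", "k3"))
})

test_that("estimation traces round-trip through the report-file interchange", {
  space <- param_space("x", 0.1, 10, scale = "linear")
  f <- function(p) (p[["x"]] - 2)^2
  fits <- run_repeats(f, space, pso_settings(swarm_size = 5, iterations = 8),
                      n_repeats = 3, master_seed = 2)
  dir <- withr::local_tempdir()
  kinpipe:::write_fit_sequence(fits, dir)
  back <- read_fit_sequence(dir)
  expect_equal(back$all_evals$objective, fits$all_evals$objective)
  expect_equal(back$all_evals$x, fits$all_evals$x)
  expect_equal(back$best_per_repeat$objective, fits$best_per_repeat$objective)
})

test_that("scan pipelines emit envelopes and per-time matrices", {
  dir <- withr::local_tempdir()
  cfg1 <- validate_config(list(
    pipeline = "single_param_scan", model = model_path(),
    output_dir = file.path(dir, "s1"),
    scan = list(parameter = "k1", min = 0.25, max = 1, count = 5),
    times = list(from = 0, to = 5, by = 1)), base_dir = dir)
  d1 <- run_pipeline(cfg1)
  env <- utils::read.delim(file.path(d1$analysis, "scan1d_envelope.tsv"))
  expect_true(all(env$min <= env$max))
  expect_true(file.exists(file.path(d1$report, "report.tex")))

  cfg2 <- validate_config(list(
    pipeline = "double_param_scan", model = model_path(),
    output_dir = file.path(dir, "s2"),
    scan = list(parameter = "insulin", values = c(0.5, 1, 2)),
    scan2 = list(parameter = "IR_beta", values = c(8, 16)),
    times = c(0, 1, 2, 5, 10), report_times = c(1, 2, 5, 10)),
    base_dir = dir)
  d2 <- run_pipeline(cfg2)
  mats <- list.files(d2$analysis, pattern = "^scan2d_t.*tsv$")
  expect_length(mats, 4 * 3) # 4 report times x 3 readouts
  M <- utils::read.delim(file.path(d2$analysis, "scan2d_t2_IR_beta_pY1164.tsv"),
                         check.names = FALSE)
  expect_equal(dim(M), c(3, 3)) # leading column + one column per scan2 value
})

test_that("the command-line interface runs and reports categorised failures", {
  cli <- system.file("cli", "kinpipe", package = "kinpipe")
  expect_true(nzchar(cli))
  res_usage <- suppressWarnings(system2("Rscript", cli, stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res_usage, "status"), 2L)

  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.yaml")
  yaml::write_yaml(list(pipeline = "nope", model = "m", output_dir = "o"), bad)
  res_bad <- suppressWarnings(system2("Rscript", c(cli, "simulate", bad),
                                      stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res_bad, "status"), 3L)

  good <- file.path(dir, "sim.yaml")
  yaml::write_yaml(list(pipeline = "simulate", model = model_path(),
                        output_dir = "cli_out", runs = 2,
                        simulator = list(kind = "ssa"),
                        times = list(from = 0, to = 2, by = 1)), good)
  res_ok <- suppressWarnings(system2("Rscript", c(cli, "simulate", good),
                                     stdout = TRUE, stderr = TRUE))
  expect_true(is.null(attr(res_ok, "status")))
  expect_true(file.exists(file.path(dir, "cli_out", "report", "report.tex")))
})
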