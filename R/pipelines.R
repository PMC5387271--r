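# Pipeline orchestration: each pipeline chains three sequential tasks --
# data generation, data analysis, report generation -- any of which can be
# toggled off in the YAML configuration. Analysis always consumes the report
# files from disk, never in-memory state, so previously generated data can be
# re-analysed under different settings without re-simulation.

LAYOUT_VERSION <- 1L

PIPELINE_NAMES <- c("simulate", "single_param_scan", "double_param_scan",
                    "param_estim")

fmt17 <- function(x) {
  if (is.numeric(x)) format(x, digits = 17, trim = TRUE) else as.character(x)
}

# deterministic TSV writer used for all raw/analysis artifacts
write_tsv <- function(df, path) {
  txt <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, , drop = FALSE], fmt17, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(colnames(df), collapse = "\t"), txt), path)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read and validate a pipeline configuration file
#'
#' Parses a YAML configuration, rejects unknown keys (naming the offender),
#' injects documented defaults, and returns a typed configuration list.
#' Relative paths (model, dataset, output directory) are resolved against
#' the configuration file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration of class `"pipeline_config"`.
#' @seealso [validate_config()] for validating an already-parsed list, and
#'   [run_pipeline()] for executing it.
#' @export
read_config <- function(path) {
  kp_check(file.exists(path), sprintf("configuration file not found: %s", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw, base_dir = dirname(normalizePath(path)))
}

#' Validate a raw pipeline configuration
#'
#' The schema (defaults in parentheses):
#' \preformatted{
#' pipeline: simulate | single_param_scan | double_param_scan | param_estim
#' model: path/to/model.yaml            # required
#' output_dir: results                  # required
#' title: ...                           # report title (pipeline name)
#' generate_data / analyse_data / generate_report: true
#' runs: 1          master_seed: 1      workers: 1
#' cluster: local                       # only 'local' is supported
#' simulator: {kind: ode|ssa, rtol: 1e-8, atol: 1e-10, command: ...}
#' times: {from: 0, to: 10, by: 0.1}    # or  times: [0, 1, 2, ...]
#' level: 0.95                          # ensemble CI of the mean
#' # param_estim only:
#' dataset: data.tsv
#' parameters: [{name: k1, lower: 1e-3, upper: 1e2, scale: log10}, ...]
#' pso: {swarm_size: 20, iterations: 80, inertia: 0.729,
#'       cognitive: 1.494, social: 1.494}
#' levels: [0.66, 0.95, 0.99]           df: 1        sd: null
#' # scans only:
#' scan:  {parameter: k1, min: ..., max: ..., count: ..., scale: linear,
#'         ref: ..., values: [...]}
#' scan2: {...}                         # double_param_scan only
#' report_times: [1, 2, 5, 10]          # double_param_scan only
#' }
#'
#' @param raw Parsed YAML as a named list.
#' @param base_dir Directory against which relative paths are resolved.
#' @return A `"pipeline_config"` list.
#' @export
validate_config <- function(raw, base_dir = ".") {
  kp_check(is.list(raw) && !is.null(raw$pipeline), "configuration needs a 'pipeline' key")
  if (!raw$pipeline %in% PIPELINE_NAMES) {
    kp_stop(sprintf("unknown pipeline '%s'; valid names: %s", raw$pipeline,
                    paste(PIPELINE_NAMES, collapse = ", ")),
            "kinpipe_config_error")
  }
  common <- c("pipeline", "model", "output_dir", "title", "generate_data",
              "analyse_data", "generate_report", "runs", "master_seed",
              "workers", "cluster", "simulator", "times", "level")
  allowed <- switch(raw$pipeline,
    simulate = common,
    single_param_scan = c(common, "scan"),
    double_param_scan = c(common, "scan", "scan2", "report_times"),
    param_estim = c(common, "dataset", "parameters", "pso", "levels", "df", "sd"))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    kp_stop(sprintf("unknown configuration key(s) for pipeline '%s': %s",
                    raw$pipeline, paste(unknown, collapse = ", ")),
            "kinpipe_config_error")
  }
  if (!is.null(raw$cluster) && !identical(raw$cluster, "local")) {
    kp_stop(sprintf("cluster type '%s' is not supported: only local execution is available",
                    raw$cluster), "kinpipe_unsupported_feature_error")
  }
  for (key in c("model", "output_dir")) {
    kp_check(!is.null(raw[[key]]), sprintf("configuration lacks required key '%s'", key))
  }
  resolve <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(base_dir, p)
  }
  sim <- raw$simulator %||% list()
  sim_unknown <- setdiff(names(sim), c("kind", "rtol", "atol", "command"))
  kp_check(length(sim_unknown) == 0L,
           sprintf("unknown simulator key(s): %s", paste(sim_unknown, collapse = ", ")))
  cfg <- list(
    pipeline = raw$pipeline,
    model = resolve(raw$model),
    output_dir = resolve(raw$output_dir),
    title = raw$title %||% sprintf("%s pipeline", raw$pipeline),
    generate_data = raw$generate_data %||% TRUE,
    analyse_data = raw$analyse_data %||% TRUE,
    generate_report = raw$generate_report %||% TRUE,
    runs = as.integer(raw$runs %||% 1L),
    master_seed = as.integer(raw$master_seed %||% 1L),
    workers = as.integer(raw$workers %||% 1L),
    simulator = simulator_spec(sim$kind %||% "ode",
                               rtol = sim$rtol %||% 1e-8,
                               atol = sim$atol %||% 1e-10,
                               command = sim$command),
    times = parse_times(raw$times %||% list(from = 0, to = 10, by = 0.1)),
    level = raw$level %||% 0.95)
  kp_check(cfg$runs >= 1L, "runs must be at least 1")
  kp_check(cfg$workers >= 1L, "workers must be at least 1")
  if (raw$pipeline == "param_estim") {
    kp_check(!is.null(raw$dataset), "param_estim requires a 'dataset' key")
    kp_check(!is.null(raw$parameters), "param_estim requires a 'parameters' key")
    pr <- raw$parameters
    cfg$dataset <- resolve(raw$dataset)
    cfg$space <- param_space(
      vapply(pr, function(p) p$name, character(1)),
      vapply(pr, function(p) as.numeric(p$lower), numeric(1)),
      vapply(pr, function(p) as.numeric(p$upper), numeric(1)),
      vapply(pr, function(p) p$scale %||% "log10", character(1)))
    ps <- raw$pso %||% list()
    ps_unknown <- setdiff(names(ps), c("swarm_size", "iterations", "inertia",
                                       "cognitive", "social"))
    kp_check(length(ps_unknown) == 0L,
             sprintf("unknown pso key(s): %s", paste(ps_unknown, collapse = ", ")))
    cfg$pso <- pso_settings(ps$swarm_size %||% 20L, ps$iterations %||% 80L,
                            ps$inertia %||% 0.729, ps$cognitive %||% 1.494,
                            ps$social %||% 1.494)
    cfg$levels <- as.numeric(raw$levels %||% c(0.66, 0.95, 0.99))
    cfg$df <- as.integer(raw$df %||% 1L)
    cfg$sd <- raw$sd
  }
  if (raw$pipeline %in% c("single_param_scan", "double_param_scan")) {
    kp_check(!is.null(raw$scan), "scan pipelines require a 'scan' key")
    cfg$scan <- parse_scan(raw$scan)
  }
  if (raw$pipeline == "double_param_scan") {
    kp_check(!is.null(raw$scan2), "double_param_scan requires a 'scan2' key")
    cfg$scan2 <- parse_scan(raw$scan2)
    cfg$report_times <- as.numeric(raw$report_times %||% cfg$times)
  }
  structure(cfg, class = "pipeline_config")
}

parse_times <- function(x) {
  if (is.list(x) && !is.null(x$from)) {
    kp_check(!is.null(x$to) && !is.null(x$by), "times needs from, to and by")
    seq(x$from, x$to, by = x$by)
  } else {
    as.numeric(unlist(x))
  }
}

parse_scan <- function(s) {
  unknown <- setdiff(names(s), c("parameter", "values", "min", "max", "count",
                                 "scale", "ref"))
  kp_check(length(unknown) == 0L,
           sprintf("unknown scan key(s): %s", paste(unknown, collapse = ", ")))
  kp_check(!is.null(s$parameter), "scan needs a 'parameter' key")
  values <- if (!is.null(s$values)) {
    as.numeric(unlist(s$values))
  } else {
    kp_check(!is.null(s$min) && !is.null(s$max) && !is.null(s$count),
             "scan needs either explicit 'values' or min/max/count")
    scan_values(s$min, s$max, s$count, scale = s$scale %||% "linear", ref = s$ref)
  }
  list(parameter = s$parameter, values = values)
}

pipeline_dirs <- function(output_dir) {
  list(root = output_dir,
       raw = file.path(output_dir, "raw"),
       analysis = file.path(output_dir, "analysis"),
       report = file.path(output_dir, "report"),
       manifest = file.path(output_dir, "manifest.json"))
}

write_manifest <- function(cfg, dirs, seeds, failures = integer()) {
  manifest <- list(
    layout_version = LAYOUT_VERSION,
    tool = "kinpipe",
    tool_version = as.character(utils::packageVersion("kinpipe")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    pipeline = cfg$pipeline,
    master_seed = cfg$master_seed,
    seeds = seeds,
    failures = failures,
    config = unclass(cfg)[!vapply(cfg, is.function, logical(1))])
  manifest$config$simulator <- unclass(cfg$simulator)
  if (!is.null(cfg$space)) manifest$config$space <- as.data.frame(cfg$space)
  if (!is.null(cfg$pso)) manifest$config$pso <- unclass(cfg$pso)
  jsonlite::write_json(manifest, dirs$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(dirs) {
  if (!file.exists(dirs$manifest)) {
    kp_stop(sprintf("no run manifest at '%s': run data generation first", dirs$manifest),
            "kinpipe_pipeline_error")
  }
  m <- jsonlite::read_json(dirs$manifest, simplifyVector = TRUE)
  if (!identical(as.integer(m$layout_version), LAYOUT_VERSION)) {
    kp_stop(sprintf("output layout version %s does not match this tool (%d); regenerate the data",
                    m$layout_version, LAYOUT_VERSION), "kinpipe_pipeline_error")
  }
  m
}

#' Run a configured pipeline
#'
#' Executes the enabled tasks of the configured pipeline in order: data
#' generation (simulations or repeated estimations, written as report files
#' under `raw/`), data analysis (statistics and figure files under
#' `analysis/`, all numbers also as TSV), and report generation (LaTeX and
#' Markdown sources under `report/`). A `manifest.json` at the output root
#' records the configuration snapshot, the derived per-repeat seeds, the tool
#' version and any failed repeats, which suffices to regenerate the raw data
#' bit-identically.
#'
#' @param cfg A `"pipeline_config"` (from [read_config()] or
#'   [validate_config()]) or the path to a YAML configuration file.
#' @param only One of `"all"` (default, honour the config toggles),
#'   `"analysis"` (skip generation, force analysis + report) or `"report"`
#'   (only re-render the report).
#' @return The output layout as a named list of directories, invisibly.
#' @export
run_pipeline <- function(cfg, only = c("all", "analysis", "report")) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  kp_check(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  only <- match.arg(only)
  if (only == "analysis") {
    cfg$generate_data <- FALSE; cfg$analyse_data <- TRUE; cfg$generate_report <- TRUE
  } else if (only == "report") {
    cfg$generate_data <- FALSE; cfg$analyse_data <- FALSE; cfg$generate_report <- TRUE
  }
  dirs <- pipeline_dirs(cfg$output_dir)
  for (d in dirs[c("root", "raw", "analysis", "report")]) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  model <- read_model_yaml(cfg$model)
  if (cfg$generate_data) generate_task(cfg, model, dirs)
  if (cfg$analyse_data) analyse_task(cfg, model, dirs)
  if (cfg$generate_report) report_task(cfg, dirs)
  invisible(dirs)
}

generate_task <- function(cfg, model, dirs) {
  unlink(list.files(dirs$raw, full.names = TRUE))
  seeds <- vapply(seq_len(cfg$runs), function(i) derive_seed(cfg$master_seed, i),
                  integer(1))
  failures <- integer()
  switch(cfg$pipeline,
    simulate = {
      if (cfg$simulator$kind == "ssa") {
        e <- simulate_ssa_ensemble(model, cfg$times, cfg$runs, cfg$master_seed,
                                   cfg$workers)
        for (i in seq_along(e$members)) {
          write_report(e$members[[i]],
                       file.path(dirs$raw, sprintf("simulation_%04d.tsv", i)))
        }
      } else {
        if (cfg$runs > 1L) {
          message("deterministic simulation: runs > 1 ignored, a single run is generated")
        }
        write_report(simulate_ode(model, cfg$times, cfg$simulator),
                     file.path(dirs$raw, "simulation_0001.tsv"))
        seeds <- seeds[1]
      }
    },
    param_estim = {
      data <- read_dataset(cfg$dataset)
      f <- make_objective(model, cfg$space, data, sd = cfg$sd)
      fits <- run_repeats(f, cfg$space, cfg$pso, cfg$runs, cfg$master_seed,
                          cfg$workers)
      failures <- fits$failed_repeats
      write_fit_sequence(fits, dirs$raw)
    },
    single_param_scan = {
      sc <- scan_1d(model, cfg$scan$parameter, cfg$scan$values, cfg$times,
                    cfg$simulator)
      write_tsv(sc$table, file.path(dirs$raw, "scan1d.tsv"))
    },
    double_param_scan = {
      sc <- scan_2d(model, cfg$scan$parameter, cfg$scan$values,
                    cfg$scan2$parameter, cfg$scan2$values, cfg$times,
                    cfg$report_times, cfg$simulator)
      write_tsv(sc$table, file.path(dirs$raw, "scan2d.tsv"))
    })
  write_manifest(cfg, dirs, seeds, failures)
  invisible(NULL)
}

analyse_task <- function(cfg, model, dirs) {
  manifest <- read_manifest(dirs)
  unlink(list.files(dirs$analysis, full.names = TRUE))
  switch(cfg$pipeline,
    simulate = analyse_simulate(cfg, dirs, manifest),
    param_estim = analyse_estimation(cfg, dirs),
    single_param_scan = analyse_scan1d(cfg, dirs),
    double_param_scan = analyse_scan2d(cfg, dirs))
  invisible(NULL)
}

analyse_simulate <- function(cfg, dirs, manifest) {
  files <- sort(list.files(dirs$raw, pattern = "^simulation_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    kp_stop(sprintf("no simulation reports found under '%s' (expected simulation_*.tsv)",
                    dirs$raw), "kinpipe_pipeline_error")
  }
  members <- lapply(files, read_report)
  if (length(members) > 1L) {
    e <- ensemble(members, manifest$seeds[seq_along(members)])
    s <- summarise_ensemble(e, cfg$level)
    write_tsv(s, file.path(dirs$analysis, "ensemble_summary.tsv"))
    fig <- file.path(dirs$analysis, "ensemble.pdf")
    grDevices::pdf(fig, width = 4 * length(unique(s$variable)), height = 4)
    plot(s)
    grDevices::dev.off()
  } else {
    tc <- members[[1]]
    write_tsv(as.data.frame(tc), file.path(dirs$analysis, "timecourse.tsv"))
    fig <- file.path(dirs$analysis, "timecourse.pdf")
    grDevices::pdf(fig, width = 6, height = 4)
    plot(tc)
    grDevices::dev.off()
  }
  invisible(NULL)
}

analyse_estimation <- function(cfg, dirs) {
  fits <- read_fit_sequence(dirs$raw)
  ple <- sampled_ple(fits, cfg$space, levels = cfg$levels, df = cfg$df)
  ci <- ple$table
  ci$flag <- as.character(ci$flag)
  write_tsv(ci, file.path(dirs$analysis, "ci_summary.tsv"))
  best <- data.frame(parameter = cfg$space$name,
                     estimate = as.numeric(coef(fits)),
                     objective = min(fits$all_evals$objective))
  write_tsv(best, file.path(dirs$analysis, "best_fit.tsv"))
  for (p in cfg$space$name) {
    s <- ple$samples[[p]]
    for (li in seq_along(cfg$levels)) {
      s[[sprintf("within_%g", 100 * cfg$levels[li])]] <-
        as.integer(s$objective <= ple$best_objective + ple$thresholds[li])
    }
    write_tsv(s, file.path(dirs$analysis, sprintf("ple_%s.tsv", p)))
  }
  co <- parameter_correlations(fits, cfg$space, level = 0.95, df = cfg$df)
  write_corr <- function(m, path) {
    df <- data.frame(parameter = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    write_tsv(df, path)
  }
  write_corr(co$best_fits, file.path(dirs$analysis, "correlations_best.tsv"))
  write_corr(co$below_threshold,
             file.path(dirs$analysis, "correlations_cl95.tsv"))
  fig <- file.path(dirs$analysis, "ple.pdf")
  grDevices::pdf(fig, width = 4 * nrow(cfg$space), height = 4)
  plot(ple)
  grDevices::dev.off()
  invisible(NULL)
}

analyse_scan1d <- function(cfg, dirs) {
  path <- file.path(dirs$raw, "scan1d.tsv")
  if (!file.exists(path)) {
    kp_stop(sprintf("no scan data at '%s': run data generation first", path),
            "kinpipe_pipeline_error")
  }
  tab <- read_tsv(path)
  sc <- structure(list(parameter = cfg$scan$parameter, values = cfg$scan$values,
                       table = tab), class = "scan_1d")
  env <- scan_envelope(sc)
  write_tsv(env, file.path(dirs$analysis, "scan1d_envelope.tsv"))
  fig <- file.path(dirs$analysis, "scan1d.pdf")
  grDevices::pdf(fig, width = 6, height = 4)
  plot(sc)
  grDevices::dev.off()
  invisible(NULL)
}

analyse_scan2d <- function(cfg, dirs) {
  path <- file.path(dirs$raw, "scan2d.tsv")
  if (!file.exists(path)) {
    kp_stop(sprintf("no scan data at '%s': run data generation first", path),
            "kinpipe_pipeline_error")
  }
  tab <- read_tsv(path)
  p1 <- cfg$scan$parameter; p2 <- cfg$scan2$parameter
  for (tt in cfg$report_times) {
    for (v in unique(tab$variable)) {
      sub <- tab[tab$time == tt & tab$variable == v, , drop = FALSE]
      M <- stats::reshape(sub[c(p1, p2, "amount")], idvar = p1,
                          timevar = p2, direction = "wide")
      colnames(M) <- sub("^amount\\.", "", colnames(M))
      write_tsv(M, file.path(dirs$analysis,
                             sprintf("scan2d_t%g_%s.tsv", tt, v)))
    }
  }
  fig <- file.path(dirs$analysis, "scan2d.pdf")
  v1 <- sort(unique(tab[[p1]])); v2 <- sort(unique(tab[[p2]]))
  grDevices::pdf(fig, width = 4 * length(cfg$report_times), height = 4)
  old <- graphics::par(mfrow = c(1, length(cfg$report_times)))
  v <- unique(tab$variable)[1]
  for (tt in cfg$report_times) {
    sub <- tab[tab$time == tt & tab$variable == v, ]
    M <- matrix(NA_real_, length(v1), length(v2))
    M[cbind(match(sub[[p1]], v1), match(sub[[p2]], v2))] <- sub$amount
    graphics::image(v1, v2, M, xlab = p1, ylab = p2,
                    main = sprintf("%s, t = %g min", v, tt))
  }
  graphics::par(old)
  grDevices::dev.off()
  invisible(NULL)
}

report_task <- function(cfg, dirs) {
  spec <- report_spec(cfg$title, cfg$pipeline, dirs$analysis)
  render_report(spec, "latex", file.path(dirs$report, "report.tex"))
  render_report(spec, "markdown", file.path(dirs$report, "report.md"))
  invisible(NULL)
}

# Estimation trace interchange: one TSV per repeat with header
# "ObjectiveValue" followed by the estimated parameter names, one row per
# objective evaluation, plus an aggregating best-fit summary.
write_fit_sequence <- function(fits, dir) {
  pars <- fits$parameters
  for (i in sort(unique(fits$all_evals$repeat_id))) {
    sub <- fits$all_evals[fits$all_evals$repeat_id == i, , drop = FALSE]
    df <- data.frame(ObjectiveValue = sub$objective, sub[pars],
                     check.names = FALSE)
    write_tsv(df, file.path(dir, sprintf("estimation_%04d.tsv", i)))
  }
  b <- fits$best_per_repeat
  df <- data.frame(Repeat = b$repeat_id, ObjectiveValue = b$objective, b[pars],
                   check.names = FALSE)
  write_tsv(df, file.path(dir, "best_fits.tsv"))
  invisible(dir)
}

#' Rebuild a fit sequence from estimation report files
#'
#' Reads the per-repeat `estimation_*.tsv` traces written during data
#' generation and reassembles the [fit_sequence()]. This is the on-disk
#' route the analysis task uses, so that generation can be disabled and
#' previous runs re-analysed.
#'
#' @param dir The raw-data directory of a `param_estim` run.
#' @return A [fit_sequence()].
#' @export
read_fit_sequence <- function(dir) {
  files <- sort(list.files(dir, pattern = "^estimation_[0-9]+\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    kp_stop(sprintf("no estimation traces found under '%s' (expected estimation_*.tsv)",
                    dir), "kinpipe_pipeline_error")
  }
  evs <- lapply(files, function(f) {
    id <- as.integer(sub("^estimation_([0-9]+)\\.tsv$", "\\1", basename(f)))
    df <- read_tsv(f)
    kp_check("ObjectiveValue" %in% colnames(df),
             sprintf("'%s' lacks an ObjectiveValue column", f))
    out <- data.frame(repeat_id = id, eval_index = seq_len(nrow(df)),
                      objective = df$ObjectiveValue,
                      df[setdiff(colnames(df), "ObjectiveValue")],
                      check.names = FALSE)
    out
  })
  fit_sequence(do.call(rbind, evs))
}
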