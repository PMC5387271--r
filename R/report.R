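# Report generation: assembles the analysis outputs of a run into a LaTeX or
# Markdown source document. The report layer never recomputes numbers -- all
# tables are read back verbatim from the analysis TSVs, and figures are the
# files the analysis task emitted.

#' Describe a report to be rendered
#'
#' Collects the tables and figure files present in an analysis directory.
#' The analysis directory must not be empty, and every referenced figure must
#' exist at render time.
#'
#' @param title Report title.
#' @param pipeline Pipeline kind (one of the four pipeline names).
#' @param analysis_dir Directory holding the analysis TSVs and figures.
#' @param figures Figure file paths; defaults to every PDF/PNG in
#'   `analysis_dir`.
#' @return An object of class `"report_spec"`.
#' @export
report_spec <- function(title, pipeline, analysis_dir, figures = NULL) {
  kp_check(dir.exists(analysis_dir),
           sprintf("analysis directory not found: %s", analysis_dir))
  content <- list.files(analysis_dir)
  if (length(content) == 0L) {
    kp_stop(sprintf("analysis directory '%s' is empty: nothing to report", analysis_dir),
            "kinpipe_report_error")
  }
  figures <- figures %||% list.files(analysis_dir, pattern = "\\.(pdf|png)$",
                                     full.names = TRUE)
  structure(list(title = title, pipeline = pipeline,
                 analysis_dir = analysis_dir, figures = figures),
            class = "report_spec")
}

#' Render a report to LaTeX or Markdown source
#'
#' Produces a self-contained source document: run metadata, the analysis
#' tables (for estimation runs, the confidence-interval summary with one row
#' per parameter and level, the best-fit table and the correlation matrices;
#' for simulation runs, a pointer to the ensemble statistics; for scans, the
#' envelope or per-time matrices) and one figure inclusion per emitted
#' figure, with paths relative to the report directory. LaTeX output uses the
#' article class with balanced environments; compiling to PDF is left to the
#' user's TeX installation.
#'
#' @param spec A [report_spec()].
#' @param fmt `"latex"` or `"markdown"`.
#' @param path Output file path (conventionally under the run's `report/`
#'   directory, next to `analysis/`).
#' @return `path`, invisibly.
#' @export
render_report <- function(spec, fmt = c("latex", "markdown"), path) {
  kp_check(inherits(spec, "report_spec"), "spec must be a report_spec")
  fmt <- match.arg(fmt)
  missing <- spec$figures[!file.exists(spec$figures)]
  if (length(missing)) {
    kp_stop(sprintf("referenced figure file(s) missing: %s",
                    paste(missing, collapse = ", ")), "kinpipe_report_error")
  }
  tables <- list()
  for (f in sort(list.files(spec$analysis_dir, pattern = "\\.tsv$",
                            full.names = TRUE))) {
    nm <- tools::file_path_sans_ext(basename(f))
    # read as text so table cells reproduce the analysis TSVs verbatim
    tables[[nm]] <- utils::read.delim(f, check.names = FALSE,
                                      colClasses = "character")
  }
  rel_fig <- vapply(spec$figures, function(f) {
    file.path("..", basename(dirname(f)), basename(f))
  }, character(1))
  lines <- if (fmt == "latex") {
    render_latex(spec, tables, rel_fig)
  } else {
    render_markdown(spec, tables, rel_fig)
  }
  writeLines(lines, path)
  invisible(path)
}

latex_escape <- function(x) {
  x <- gsub("\\", "\\textbackslash{}", x, fixed = TRUE)
  for (ch in c("&", "%", "$", "#", "_", "{", "}")) {
    x <- gsub(ch, paste0("\\", ch), x, fixed = TRUE)
  }
  x
}

latex_table <- function(df, caption) {
  align <- paste(rep("l", ncol(df)), collapse = "")
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste0(paste(latex_escape(vapply(df[i, , drop = FALSE], fmt17, character(1))),
                 collapse = " & "), " \\\\")
  }, character(1))
  c(sprintf("\\begin{table}[ht]\\centering"),
    sprintf("\\caption{%s}", latex_escape(caption)),
    sprintf("\\begin{tabular}{%s}", align),
    "\\hline",
    paste0(paste(latex_escape(colnames(df)), collapse = " & "), " \\\\"),
    "\\hline",
    body,
    "\\hline",
    "\\end{tabular}",
    "\\end{table}")
}

md_table <- function(df) {
  c(paste("|", paste(colnames(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    vapply(seq_len(nrow(df)), function(i) {
      paste("|", paste(vapply(df[i, , drop = FALSE], fmt17, character(1)),
                       collapse = " | "), "|")
    }, character(1)))
}

table_caption <- function(nm) {
  switch(nm,
    ci_summary = "Confidence intervals per parameter and confidence level",
    best_fit = "Global best-fit parameter estimates",
    correlations_best = "Parameter correlations over the per-repeat best fits",
    correlations_cl95 = "Parameter correlations below the 95% threshold",
    ensemble_summary = "Stochastic ensemble summary statistics",
    timecourse = "Deterministic time course",
    scan1d_envelope = "Single-parameter scan envelope",
    sprintf("Analysis table: %s", nm))
}

# large per-point tables are referenced, not inlined
INLINE_TABLES <- c("ci_summary", "best_fit", "correlations_best",
                   "correlations_cl95")

render_latex <- function(spec, tables, figures) {
  out <- c(
    "\\documentclass{article}",
    "\\usepackage{graphicx}",
    "\\usepackage[margin=2.5cm]{geometry}",
    sprintf("\\title{%s}", latex_escape(spec$title)),
    "\\author{kinpipe}",
    "\\begin{document}",
    "\\maketitle",
    sprintf("\\section{Pipeline: %s}", latex_escape(spec$pipeline)))
  for (nm in names(tables)) {
    if (nm %in% INLINE_TABLES) {
      out <- c(out, latex_table(tables[[nm]], table_caption(nm)))
    } else {
      out <- c(out, sprintf("Full data table \\texttt{%s.tsv} (%d rows) is provided alongside this report.",
                            latex_escape(nm), nrow(tables[[nm]])))
    }
  }
  if (length(figures)) {
    out <- c(out, "\\section{Figures}")
    for (f in figures) {
      out <- c(out,
               "\\begin{figure}[ht]\\centering",
               sprintf("\\includegraphics[width=0.9\\textwidth]{%s}", f),
               "\\end{figure}")
    }
  }
  c(out, "\\end{document}")
}

render_markdown <- function(spec, tables, figures) {
  out <- c(sprintf("# %s", spec$title), "",
           sprintf("Pipeline: `%s`", spec$pipeline), "")
  for (nm in names(tables)) {
    if (nm %in% INLINE_TABLES) {
      out <- c(out, sprintf("## %s", table_caption(nm)), "",
               md_table(tables[[nm]]), "")
    } else {
      out <- c(out, sprintf("Full data table `%s.tsv` (%d rows) is provided alongside this report.",
                            nm, nrow(tables[[nm]])), "")
    }
  }
  if (length(figures)) {
    out <- c(out, "## Figures", "")
    for (f in figures) {
      out <- c(out, sprintf("![figure](%s)", f), "")
    }
  }
  out
}
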