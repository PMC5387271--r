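# Report files are the interchange artifact between the data-generation and
# analysis tasks: plain TSV, first row a header whose first field is literally
# "Time", remaining fields the reported variable names; decimal points, no
# thousands separators; values emitted with 17 significant digits so that a
# write/read round trip reproduces the doubles.

#' Write a time course as a report file
#'
#' @param tc A [time_course()].
#' @param path Output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_report <- function(tc, path) {
  kp_check(inherits(tc, "time_course"), "tc must be a time_course")
  header <- paste(c("Time", tc$variable_names), collapse = "\t")
  rows <- vapply(seq_along(tc$times), function(i) {
    paste(format(c(tc$times[i], tc$values[i, ]), digits = 17, trim = TRUE,
                 scientific = FALSE), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a report file into a time course
#'
#' Columns are matched by header name, not position; only the `Time` column
#' must come first. Malformed files (missing header, no data rows, wrong field
#' counts, non-numeric entries) raise a report-format error naming the
#' offending line.
#'
#' @param path Path to a report TSV.
#' @return A [time_course()].
#' @export
read_report <- function(path) {
  kp_check(file.exists(path), sprintf("report file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) {
    kp_stop(sprintf("report file '%s' is empty", path), "kinpipe_report_format_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "Time") {
    kp_stop(sprintf("report file '%s', line 1: header must start with 'Time' and name at least one variable", path),
            "kinpipe_report_format_error")
  }
  if (length(lines) < 2L) {
    kp_stop(sprintf("report file '%s' has a header but no data rows", path),
            "kinpipe_report_format_error")
  }
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, length(header) - 1L,
                 dimnames = list(NULL, header[-1]))
  times <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      kp_stop(sprintf("report file '%s', line %d: %d fields, expected %d",
                      path, i + 1L, length(fields), length(header)),
              "kinpipe_report_format_error")
    }
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num)) {
      kp_stop(sprintf("report file '%s', line %d: non-numeric entry", path, i + 1L),
              "kinpipe_report_format_error")
    }
    times[i] <- num[1]
    vals[i, ] <- num[-1]
  }
  time_course(times, vals)
}
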