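#' Read a time-series CSV
#'
#' Comma-separated, `.` decimal, `#`-prefixed metadata header lines. The
#' time column (`time_ms`, `time`, or `t`) must be strictly increasing;
#' schema violations name the offending column.
#'
#' @param path CSV file path.
#' @param time_col expected time column name; autodetected among
#'   `time_ms`, `time`, `t` when `NULL`.
#' @return data.frame with the parsed series; metadata lines in
#'   `attr(, "meta")`.
#' @export
read_timeseries <- function(path, time_col = NULL) {
  lines <- readLines(path, n = 50L)
  meta <- sub("^#\\s?", "", grep("^#", lines, value = TRUE))
  df <- read.csv(path, comment.char = "#")
  if (is.null(time_col)) {
    time_col <- intersect(c("time_ms", "time", "t"), names(df))[1]
    if (is.na(time_col))
      stop("schema error: no time column (expected one of time_ms, time, t)")
  } else if (!time_col %in% names(df)) {
    stop("schema error: missing column '", time_col, "'")
  }
  tt <- df[[time_col]]
  if (anyNA(tt) || !is.numeric(tt))
    stop("schema error: column '", time_col, "' must be numeric without gaps")
  if (any(diff(tt) == 0))
    stop("schema error: duplicated time stamps in column '", time_col, "'")
  if (any(diff(tt) < 0))
    stop("schema error: column '", time_col, "' must be monotone increasing")
  if (ncol(df) < 2L) stop("schema error: no value column beside the time column")
  attr(df, "meta") <- meta
  df
}

#' Write a time-series CSV with metadata header
#'
#' Writes `#`-prefixed metadata lines (tool version, units, any extra
#' entries) followed by a plain CSV body, the format [read_timeseries()]
#' parses back bit-exactly.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named character vector of extra metadata lines.
#' @export
write_timeseries <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("anisohead %s",
                   as.character(utils::packageVersion("anisohead"))),
           "units: time ms, stress kPa, length mm",
           if (length(meta))
             paste0(names(meta), ifelse(nzchar(names(meta)), ": ", ""), meta))
  writeLines(paste0("# ", hdr), con)
  out <- df
  for (j in seq_along(out))  # 17 significant digits round-trip doubles
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
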