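## Plain-text readers/writers for signals, label tracks and task windows.
## Signals: CSV, header comments `# rate_hz=<x>` and `# t0_s=<x>` followed by
## a channel-name header row. Labels: CSV with fixed columns, or a JSON mirror.

#' Write / read a TimeSeries as CSV
#'
#' The sampling rate and start offset are stored as `# rate_hz=` / `# t0_s=`
#' comment lines before the channel-name header. Round trips are lossless to
#' floating-point representation.
#'
#' @param series A `TimeSeries`.
#' @param path File path.
#' @return `read_signals()` returns a `TimeSeries`; `write_signals()` the path,
#'   invisibly.
#' @export
write_signals <- function(series, path) {
  stopifnot(inherits(series, "TimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.17g", series$rate_hz), con)
  writeLines(sprintf("# t0_s=%.17g", series$t0_s), con)
  writeLines(paste(colnames(series$samples), collapse = ","), con)
  if (nrow(series$samples) > 0) {
    utils::write.table(format(series$samples, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  rate <- sub("^#\\s*rate_hz=", "", grep("rate_hz=", meta, value = TRUE))
  if (length(rate) != 1) stop("signal file is missing '# rate_hz=' metadata")
  t0 <- sub("^#\\s*t0_s=", "", grep("t0_s=", meta, value = TRUE))
  t0 <- if (length(t0) == 1) as.numeric(t0) else 0
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) == 0) {
    m <- matrix(numeric(0), ncol = length(header))
  } else {
    fields <- strsplit(data_lines, ",", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(header))) stop("ragged rows in signal CSV")
    m <- matrix(as.numeric(unlist(fields)), ncol = length(header), byrow = TRUE)
  }
  time_series(m, rate_hz = as.numeric(rate), channel_names = header, t0_s = t0)
}

#' Write / read a LabelTrack (CSV or JSON)
#'
#' CSV columns: `start_s,end_s,activity,phase,foot`. JSON mirrors the same
#' fields. Format is chosen by the file extension (`.json` for JSON).
#'
#' @param track A `LabelTrack`.
#' @param path File path (`.csv` or `.json`).
#' @return `read_labels()` returns a `LabelTrack`.
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "LabelTrack"))
  df <- track$segments
  df$foot <- rep(track$foot, length.out = max(nrow(df), 0))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(foot = track$foot, segments = track$segments),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    segs <- as.data.frame(obj$segments, stringsAsFactors = FALSE)
    if (nrow(segs) == 0) return(label_track(NULL, foot = obj$foot))
    return(label_track(segments(segs$start_s, segs$end_s, segs$activity,
                                segs$phase), foot = obj$foot))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "activity", "phase", "foot")
  if (!all(need %in% names(df))) {
    stop("label CSV must have columns: ", paste(need, collapse = ", "))
  }
  foot <- if (nrow(df) > 0) df$foot[1] else "left"
  label_track(segments(df$start_s, df$end_s, df$activity, df$phase),
              foot = foot)
}

#' Write / read task windows as CSV
#'
#' Columns `start_s,end_s,task_name,allowed_activities`, the last a
#' semicolon-separated activity list.
#'
#' @param tasks Task-window data.frame from [task_windows()].
#' @param path File path.
#' @export
write_tasks <- function(tasks, path) {
  df <- tasks
  df$allowed_activities <- vapply(tasks$allowed_activities,
                                  paste, character(1), collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tasks
#' @export
read_tasks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  task_windows(df$start_s, df$end_s, df$task_name,
               strsplit(df$allowed_activities, ";", fixed = TRUE))
}
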