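#' @useDynLib cyclephase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx fft rnorm runif sd var setNames median
#' @importFrom utils head tail read.csv write.csv
"_PACKAGE"

## Vocabulary ----------------------------------------------------------------

#' Activity and phase vocabularies
#'
#' `activities()` returns the full set of recognised activity labels;
#' `cyclic_activities()` those that carry swing/stance phase labels;
#' `simple_activities()` those without any cycle structure. Cycling is cyclic
#' but phase-less: only whole cycles are delimited.
#'
#' @return Character vector of labels.
#' @export
activities <- function() {
  c("walk", "jog", "run", "stairs", "jump", "hop", "skip", "side_step",
    "run_on_spot", "cycle", "sit", "rest", "unknown")
}

#' @rdname activities
#' @export
cyclic_activities <- function() {
  c("walk", "jog", "run", "stairs", "jump", "hop", "skip", "side_step",
    "run_on_spot")
}

#' @rdname activities
#' @export
simple_activities <- function() c("sit", "rest")

phases <- function() c("swing", "stance", "none")

phaseless_activities <- function() c("sit", "rest", "unknown", "cycle")

## TimeSeries ----------------------------------------------------------------

#' Uniformly sampled multichannel time series
#'
#' Container for sensor data: a frames-by-channels numeric matrix, a sampling
#' rate in Hz and the time offset of the first sample. Timestamps are
#' implicit, `t(i) = t0_s + (i - 1) / rate_hz`.
#'
#' @param samples Numeric matrix (frames x channels) or a vector (one channel).
#' @param rate_hz Positive sampling rate in Hz.
#' @param channel_names Optional channel identifiers; defaults to the matrix
#'   column names.
#' @param t0_s Time of the first sample in seconds.
#' @return An object of class `TimeSeries`.
#' @export
time_series <- function(samples, rate_hz, channel_names = NULL, t0_s = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  if (is.null(channel_names)) channel_names <- colnames(samples)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples)) {
    stop("channel_names length must match the number of columns")
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s)),
    class = "TimeSeries"
  )
}

#' @export
print.TimeSeries <- function(x, ...) {
  cat(sprintf("<TimeSeries> %d frames x %d channels @ %g Hz, t0 = %g s\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz, x$t0_s))
  cat("channels:", paste(colnames(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' Frame timestamps of a TimeSeries
#' @param series A `TimeSeries`.
#' @return Numeric vector of per-frame times in seconds.
#' @export
ts_times <- function(series) {
  n <- nrow(series$samples)
  if (n == 0) return(numeric(0))
  series$t0_s + (seq_len(n) - 1) / series$rate_hz
}

#' Extract one channel of a TimeSeries as a numeric vector
#' @param series A `TimeSeries`.
#' @param channel Channel name or index.
#' @return Numeric vector.
#' @export
ts_channel <- function(series, channel) {
  if (is.character(channel) && !channel %in% colnames(series$samples)) {
    stop("unknown channel: ", channel)
  }
  as.numeric(series$samples[, channel])
}

## Segments and LabelTrack ---------------------------------------------------

#' Build a segment table
#'
#' Segments use half-open intervals `[start_s, end_s)` in seconds. Phase must
#' be `"none"` for phase-less activities (sit, rest, unknown, cycle) and
#' swing/stance for the cyclic ones.
#'
#' @param start_s,end_s Numeric vectors of segment bounds (seconds).
#' @param activity Character vector of activity labels.
#' @param phase Character vector of phase labels.
#' @return A data.frame with columns start_s, end_s, activity, phase.
#' @export
segments <- function(start_s, end_s, activity, phase) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   activity = as.character(activity),
                   phase = as.character(phase),
                   stringsAsFactors = FALSE)
  df
}

#' Per-foot annotation track
#'
#' An ordered list of non-overlapping labeled segments for one foot. Rest is
#' background: any time not covered by a segment is implicitly rest, so tracks
#' normally carry only non-rest segments (plus sit).
#'
#' @param segs Segment data.frame as built by [segments()].
#' @param foot `"left"` or `"right"`.
#' @param validate Check basic structural invariants (sorting, overlap, enums).
#' @return An object of class `LabelTrack`.
#' @export
label_track <- function(segs, foot = "left", validate = TRUE) {
  if (is.null(segs) || nrow(segs) == 0) {
    segs <- segments(numeric(0), numeric(0), character(0), character(0))
  }
  foot <- match.arg(foot, c("left", "right"))
  segs <- segs[order(segs$start_s), , drop = FALSE]
  rownames(segs) <- NULL
  tr <- structure(list(foot = foot, segments = segs), class = "LabelTrack")
  if (validate) assert_track_basic(tr)
  tr
}

#' @export
print.LabelTrack <- function(x, ...) {
  cat(sprintf("<LabelTrack> foot = %s, %d segments\n", x$foot,
              nrow(x$segments)))
  if (nrow(x$segments) > 0) {
    cat(sprintf("  span [%.3f, %.3f] s; activities: %s\n",
                min(x$segments$start_s), max(x$segments$end_s),
                paste(unique(x$segments$activity), collapse = ", ")))
  }
  invisible(x)
}

n_segments <- function(track) nrow(track$segments)

# Structural invariants that every track must satisfy (predicted or reference).
assert_track_basic <- function(track) {
  segs <- track$segments
  if (nrow(segs) == 0) return(invisible(TRUE))
  if (any(!segs$activity %in% activities())) {
    stop("unknown activity label: ",
         paste(setdiff(segs$activity, activities()), collapse = ", "))
  }
  if (any(!segs$phase %in% phases())) {
    stop("unknown phase label: ",
         paste(setdiff(segs$phase, phases()), collapse = ", "))
  }
  if (any(segs$end_s <= segs$start_s)) stop("segment with end_s <= start_s")
  bad_none <- segs$activity %in% phaseless_activities() & segs$phase != "none"
  bad_phase <- !segs$activity %in% phaseless_activities() & segs$phase == "none"
  if (any(bad_none)) stop("phase-less activity with a swing/stance phase label")
  if (any(bad_phase)) stop("cyclic activity segment with phase = none")
  if (nrow(segs) > 1) {
    if (any(diff(segs$start_s) < 0)) stop("segments not sorted")
    if (any(segs$start_s[-1] < segs$end_s[-nrow(segs)] - 1e-9)) {
      stop("overlapping segments")
    }
  }
  invisible(TRUE)
}

#' Check the full label-definition invariant suite on a track
#'
#' Beyond basic structure, checks the cycle-phase conventions: within each
#' bout of a cyclic activity, phases strictly alternate swing/stance and the
#' bout starts and ends with a swing. A single stance separating two
#' different non-rest activities at a transition is allowed.
#'
#' @param track A `LabelTrack`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_track_invariants <- function(track) {
  assert_track_basic(track)
  segs <- track$segments
  if (nrow(segs) == 0) return(invisible(TRUE))
  b <- bouts_of(track)
  n <- nrow(segs)
  contiguous_other <- function(j, k) {
    # segment k is a different cyclic activity touching segment j
    k >= 1 && k <= n &&
      abs(segs$start_s[max(j, k)] - segs$end_s[min(j, k)]) <= 1e-6 &&
      segs$activity[k] != segs$activity[j] &&
      segs$activity[k] %in% cyclic_activities()
  }
  for (i in seq_len(nrow(b))) {
    idx <- seq(b$first[i], b$last[i])
    ph <- segs$phase[idx]
    act <- segs$activity[idx]
    if (act[1] %in% phaseless_activities()) next
    first <- idx[1]; last <- idx[length(idx)]
    # a single stance separating two adjacent bouts of different activities
    # is allowed at a transition
    if (ph[1] != "swing" &&
        !(ph[1] == "stance" && contiguous_other(first, first - 1L))) {
      stop("bout does not start with swing (", act[1], ")")
    }
    if (ph[length(ph)] != "swing" &&
        !(ph[length(ph)] == "stance" && contiguous_other(last, last + 1L))) {
      stop("bout does not end with swing (", act[1], ")")
    }
    if (length(ph) > 1 && any(ph[-1] == ph[-length(ph)])) {
      stop("phases do not alternate within bout (", act[1], ")")
    }
  }
  invisible(TRUE)
}

# Bout table: maximal contiguous runs of a single non-rest activity.
# Contiguity tolerance is 1e-6 s. A stance of a *different* non-rest activity
# wedged between two bouts is its own (separator) run.
bouts_of <- function(track) {
  segs <- track$segments
  n <- nrow(segs)
  if (n == 0) {
    return(data.frame(first = integer(0), last = integer(0),
                      activity = character(0)))
  }
  new_bout <- c(TRUE, (segs$activity[-1] != segs$activity[-n]) |
                  (segs$start_s[-1] > segs$end_s[-n] + 1e-6))
  id <- cumsum(new_bout)
  first <- match(unique(id), id)
  last <- n + 1L - match(unique(id), rev(id))
  data.frame(first = first, last = last,
             activity = segs$activity[first], stringsAsFactors = FALSE)
}

## TaskWindow ----------------------------------------------------------------

#' Protocol task windows
#'
#' A task window is a protocol-level interval carrying the set of activities
#' allowed inside it. Rest is always allowed.
#'
#' @param start_s,end_s Interval bounds in seconds.
#' @param task_name Identifier for the task.
#' @param allowed_activities List of character vectors (one per window).
#' @return A data.frame with a list-column `allowed_activities`.
#' @export
task_windows <- function(start_s, end_s, task_name, allowed_activities) {
  if (is.character(allowed_activities)) {
    allowed_activities <- rep(list(allowed_activities), length(start_s))
  }
  allowed_activities <- lapply(allowed_activities, function(a) {
    a <- unique(c(as.character(a), "rest"))
    bad <- setdiff(a, activities())
    if (length(bad) > 0) stop("unknown activity in task window: ",
                              paste(bad, collapse = ", "))
    a
  })
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   task_name = as.character(task_name),
                   stringsAsFactors = FALSE)
  if (any(df$end_s <= df$start_s)) stop("task window with end_s <= start_s")
  df$allowed_activities <- allowed_activities
  df
}

## Boundary events -----------------------------------------------------------

#' Boundary events of a label track
#'
#' A boundary event is a segmentation point between two activities or phases:
#' every segment start and end, with shared endpoints de-duplicated. For a
#' contiguous n-segment track this yields n + 1 events; a gap contributes both
#' its opening and closing time.
#'
#' @param track A `LabelTrack`.
#' @param tol_s Endpoints closer than this are treated as one boundary.
#' @return data.frame with columns `time_s`, `left_activity`, `left_phase`,
#'   `right_activity`, `right_phase` (NA on the open side), sorted by time.
#' @export
track_to_boundaries <- function(track, tol_s = 1e-6) {
  assert_track_basic(track)
  segs <- track$segments
  if (nrow(segs) == 0) {
    return(data.frame(time_s = numeric(0), left_activity = character(0),
                      left_phase = character(0), right_activity = character(0),
                      right_phase = character(0), stringsAsFactors = FALSE))
  }
  ev <- data.frame(
    time_s = c(segs$start_s, segs$end_s),
    left_activity = c(rep(NA_character_, nrow(segs)), segs$activity),
    left_phase = c(rep(NA_character_, nrow(segs)), segs$phase),
    right_activity = c(segs$activity, rep(NA_character_, nrow(segs))),
    right_phase = c(segs$phase, rep(NA_character_, nrow(segs))),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$time_s), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    j <- nrow(out)
    if (ev$time_s[i] - out$time_s[j] <= tol_s) {
      # merge a shared end/start pair into one interior boundary
      if (is.na(out$left_activity[j]) && !is.na(ev$left_activity[i])) {
        out$left_activity[j] <- ev$left_activity[i]
        out$left_phase[j] <- ev$left_phase[i]
      }
      if (is.na(out$right_activity[j]) && !is.na(ev$right_activity[i])) {
        out$right_activity[j] <- ev$right_activity[i]
        out$right_phase[j] <- ev$right_phase[i]
      }
    } else {
      out <- rbind(out, ev[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
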