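## Pressure-insole edge detection: rising/falling derivative peaks per
## channel, aggregation to ground-contact intervals, and conversion to a
## phase-level LabelTrack using the protocol task and the rest mask.

#' Normalize pressure channels to [0, 1]
#'
#' Per-channel min-max normalization over the recording, the scaling the
#' edge-detector strength threshold is defined against.
#'
#' @param pressure `TimeSeries` of pressure channels.
#' @param channels Channels to normalize (default: all).
#' @return `TimeSeries` with channels scaled to `[0, 1]`.
#' @export
normalize_pressure <- function(pressure, channels = NULL) {
  out <- pressure
  idx <- if (is.null(channels)) seq_len(ncol(pressure$samples)) else channels
  for (j in idx) {
    v <- pressure$samples[, j]
    rng <- range(v)
    if (diff(rng) == 0) stop("constant pressure channel cannot be normalized")
    out$samples[, j] <- (v - rng[1]) / diff(rng)
  }
  out
}

#' Detect rising and falling edges on one pressure channel
#'
#' Finds the positive and negative peaks of the first derivative of the
#' (filtered, `[0,1]`-normalized) pressure signal. Local extrema of the
#' derivative whose magnitude exceeds `min_strength` become events: rising
#' for positive peaks (loading), falling for negative (unloading).
#'
#' @param pressure Normalized, filtered pressure `TimeSeries`.
#' @param channel Channel index (1-5) or name.
#' @param min_strength Minimum derivative magnitude, in normalized pressure
#'   units per second.
#' @return data.frame with columns `time_s`, `polarity`, `channel`, `strength`.
#' @export
detect_channel_edges <- function(pressure, channel, min_strength = 8.0) {
  x <- ts_channel(pressure, channel)
  if (length(x) > 0 && (min(x) < -0.01 || max(x) > 1.01)) {
    stop("pressure channel is not normalized to [0, 1]")
  }
  rate <- pressure$rate_hz
  if (length(x) < 3) {
    return(data.frame(time_s = numeric(0), polarity = character(0),
                      channel = integer(0), strength = numeric(0)))
  }
  d <- diff(x) * rate
  # local extrema of the derivative (plateau-safe: first sample wins)
  n <- length(d)
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n],
              FALSE) & d > min_strength
  is_min <- c(FALSE, d[2:(n - 1)] < d[1:(n - 2)] & d[2:(n - 1)] <= d[3:n],
              FALSE) & d < -min_strength
  ti <- ts_times(pressure)
  mid <- (ti[-length(ti)] + ti[-1]) / 2   # derivative lives between samples
  ev <- rbind(
    data.frame(time_s = mid[is_max],
               polarity = rep("rising", sum(is_max)),
               strength = d[is_max], stringsAsFactors = FALSE),
    data.frame(time_s = mid[is_min],
               polarity = rep("falling", sum(is_min)),
               strength = -d[is_min], stringsAsFactors = FALSE)
  )
  if (nrow(ev) == 0) {
    return(data.frame(time_s = numeric(0), polarity = character(0),
                      channel = integer(0), strength = numeric(0)))
  }
  ev$channel <- if (is.character(channel)) {
    match(channel, colnames(pressure$samples))
  } else as.integer(channel)
  ev <- ev[order(ev$time_s), c("time_s", "polarity", "channel", "strength")]
  rownames(ev) <- NULL
  ev
}

#' Aggregate per-channel edges into ground-contact intervals
#'
#' Reconstruction of the empirical rule set: (a) events of one polarity within
#' `cluster_s` of each other form a cluster; contact start is the earliest
#' rising event of its cluster (heel loads first), contact end the latest
#' falling event (toe unloads last); (b) rising/falling alternation is
#' enforced by keeping the stronger of two same-polarity neighbors; (c)
#' contacts shorter than `min_stance_s` and gaps shorter than `min_swing_s`
#' are dropped/merged. Unpaired leading falling or trailing rising events are
#' dropped.
#'
#' @param edges data.frame of events from [detect_channel_edges()] (all
#'   channels concatenated), or a list of such data.frames.
#' @param cluster_s Cluster width in seconds.
#' @param min_stance_s,min_swing_s Minimum contact / gap durations.
#' @return data.frame with columns `start_s`, `end_s` (sorted, disjoint).
#' @export
aggregate_edges <- function(edges, cluster_s = 0.100, min_stance_s = 0.08,
                            min_swing_s = 0.08) {
  if (is.list(edges) && !is.data.frame(edges)) edges <- do.call(rbind, edges)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (is.null(edges) || nrow(edges) == 0) return(empty)
  edges <- edges[order(edges$time_s), , drop = FALSE]

  cluster_one <- function(ev, keep_first) {
    if (nrow(ev) == 0) return(ev)
    grp <- cumsum(c(TRUE, diff(ev$time_s) > cluster_s))
    out <- do.call(rbind, lapply(split(ev, grp), function(g) {
      g[if (keep_first) 1L else nrow(g), , drop = FALSE]
    }))
    rownames(out) <- NULL
    out
  }
  rises <- cluster_one(edges[edges$polarity == "rising", , drop = FALSE], TRUE)
  falls <- cluster_one(edges[edges$polarity == "falling", , drop = FALSE], FALSE)
  ev <- rbind(rises, falls)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  # enforce alternation: among same-polarity neighbors keep the stronger
  repeat {
    same <- which(ev$polarity[-1] == ev$polarity[-nrow(ev)])
    if (length(ev$polarity) < 2 || length(same) == 0) break
    i <- same[1]
    drop <- if (ev$strength[i] >= ev$strength[i + 1]) i + 1L else i
    ev <- ev[-drop, , drop = FALSE]
  }
  # pair rising -> falling
  if (nrow(ev) > 0 && ev$polarity[1] == "falling") ev <- ev[-1, , drop = FALSE]
  if (nrow(ev) > 0 && ev$polarity[nrow(ev)] == "rising") {
    ev <- ev[-nrow(ev), , drop = FALSE]
  }
  if (nrow(ev) < 2) return(empty)
  st <- data.frame(start_s = ev$time_s[ev$polarity == "rising"],
                   end_s = ev$time_s[ev$polarity == "falling"])
  # merge gaps shorter than min_swing_s, then drop short contacts
  if (nrow(st) > 1) {
    keep_gap <- st$start_s[-1] - st$end_s[-nrow(st)] >= min_swing_s
    grp <- cumsum(c(TRUE, keep_gap))
    st <- data.frame(start_s = tapply(st$start_s, grp, min),
                     end_s = tapply(st$end_s, grp, max))
  }
  st <- st[st$end_s - st$start_s >= min_stance_s, , drop = FALSE]
  rownames(st) <- NULL
  st
}

#' Convert ground-contact intervals to a phase-level LabelTrack
#'
#' Gaps between consecutive contacts are swing phases of the task's cyclic
#' activity. Contact intervals mostly covered by the rest mask are treated as
#' standing rest (background, omitted); other contacts between two swings
#' become stance segments. The result is passed through the post-processing
#' rules, so bouts start and end with a swing.
#'
#' @param stances data.frame `start_s`/`end_s` from [aggregate_edges()].
#' @param rest Logical rest mask sampled at `rest_rate_hz`.
#' @param rest_rate_hz Sampling rate of the rest mask.
#' @param task One task-window row (data.frame); its single cyclic allowed
#'   activity names the bout activity.
#' @param foot Which foot the track belongs to.
#' @return A `LabelTrack` of swing/stance segments.
#' @export
edges_to_track <- function(stances, rest, rest_rate_hz, task, foot = "left") {
  cyc <- setdiff(task$allowed_activities[[1]], c("rest", "sit"))
  if (length(cyc) != 1) {
    stop("edge detection needs a task with exactly one cyclic activity; got: ",
         paste(cyc, collapse = ", "))
  }
  # clip contacts to the task window
  st <- stances[stances$end_s > task$start_s & stances$start_s < task$end_s, ,
                drop = FALSE]
  if (nrow(st) == 0) return(label_track(NULL, foot = foot))
  rest_frac <- function(a, b) {
    i0 <- max(1L, floor(a * rest_rate_hz) + 1L)
    i1 <- min(length(rest), ceiling(b * rest_rate_hz))
    if (i1 < i0) return(0)
    mean(rest[i0:i1])
  }
  is_rest <- vapply(seq_len(nrow(st)),
                    function(i) rest_frac(st$start_s[i], st$end_s[i]) > 0.5,
                    logical(1))
  segs <- NULL
  for (i in seq_len(nrow(st))[-1]) {
    sw_start <- st$end_s[i - 1]
    sw_end <- st$start_s[i]
    if (sw_end <= sw_start) next
    segs <- rbind(segs, segments(sw_start, sw_end, cyc, "swing"))
  }
  # stance segments: non-rest contacts with a swing on both sides
  for (i in seq_len(nrow(st))) {
    if (is_rest[i]) next
    has_before <- i > 1 && st$start_s[i] > st$end_s[i - 1]
    has_after <- i < nrow(st) && st$end_s[i] < st$start_s[i + 1]
    if (has_before && has_after) {
      segs <- rbind(segs, segments(st$start_s[i], st$end_s[i], cyc, "stance"))
    }
  }
  if (is.null(segs) || nrow(segs) == 0) return(label_track(NULL, foot = foot))
  tr <- label_track(segs[order(segs$start_s), , drop = FALSE], foot = foot)
  enforce_swing_boundaries(merge_consecutive(tr))
}

#' Run edge detection end to end on one insole recording
#'
#' Normalizes and low-pass filters the pressure channels, detects per-channel
#' edges, aggregates them to ground contacts, and builds one track per task
#' window, concatenated into a single per-foot `LabelTrack`.
#'
#' @param insole Pressure `TimeSeries` (channels `p1`..`p5`).
#' @param imu Matching shoe-IMU `TimeSeries` (for the rest mask).
#' @param tasks Task windows.
#' @param foot Foot label.
#' @param config Configuration list, see [default_config()].
#' @return A `LabelTrack`.
#' @export
edge_detect_track <- function(insole, imu, tasks, foot = "left",
                              config = default_config()) {
  pch <- intersect(paste0("p", 1:5), colnames(insole$samples))
  pr <- time_series(insole$samples[, pch, drop = FALSE],
                    rate_hz = insole$rate_hz, t0_s = insole$t0_s)
  pr <- normalize_pressure(lowpass(pr, config$lowpass$cutoff_hz,
                                   config$lowpass$order))
  pr$samples <- pmin(pmax(pr$samples, 0), 1)
  ev <- do.call(rbind, lapply(seq_along(pch), function(j) {
    detect_channel_edges(pr, j, config$edges$min_strength)
  }))
  st <- aggregate_edges(ev, config$edges$cluster_s, config$edges$min_stance_s,
                        config$edges$min_swing_s)
  rm_mask <- rest_mask(imu, config$rest$window_s, config$rest$threshold)
  segs <- NULL
  for (i in seq_len(nrow(tasks))) {
    cyc <- setdiff(tasks$allowed_activities[[i]], c("rest", "sit"))
    if (length(cyc) != 1 || cyc == "cycle") next
    tr <- edges_to_track(st, rm_mask, imu$rate_hz, tasks[i, , drop = FALSE],
                         foot = foot)
    segs <- rbind(segs, tr$segments)
  }
  if (is.null(segs)) return(label_track(NULL, foot = foot))
  merge_consecutive(label_track(segs[order(segs$start_s), , drop = FALSE],
                                foot = foot))
}
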