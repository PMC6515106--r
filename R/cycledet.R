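## Unsupervised cycle segmentation for phase-less activities (cycling):
## simple peak detection on the normalized GZ channel, and a local cyclicity
## estimator that only places anchors inside locally periodic regions.

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
          FALSE))
}

#' Peak detection on the normalized GZ channel
#'
#' Standard peak picking: local maxima at least `min_height` tall (relative
#' to the max-abs-normalized signal) are accepted greedily in descending
#' height order, subject to a pairwise minimum distance (400 ms and 0.5 by
#' default). Ties in height go to the earlier peak.
#'
#' @param gz_norm Numeric vector, max-abs normalized GZ.
#' @param rate_hz Sampling rate.
#' @param min_distance_s Minimum distance between accepted peaks.
#' @param min_height Minimum peak height.
#' @param t0_s Time of the first sample.
#' @return List of class `CycleMarks`: `times_s`, `method = "pd"`.
#' @export
detect_pd <- function(gz_norm, rate_hz, min_distance_s = 0.4,
                      min_height = 0.5, t0_s = 0) {
  if (length(gz_norm) > 0 && max(abs(gz_norm)) > 1 + 1e-8) {
    stop("input must be max-abs normalized (|x| <= 1)")
  }
  cand <- local_maxima(gz_norm)
  cand <- cand[gz_norm[cand] >= min_height]
  # greedy by descending height, earlier peak wins ties
  ord <- cand[order(-gz_norm[cand], cand)]
  min_gap <- min_distance_s * rate_hz
  acc <- integer(0)
  for (i in ord) {
    if (all(abs(acc - i) >= min_gap)) acc <- c(acc, i)
  }
  acc <- sort(acc)
  structure(list(times_s = t0_s + (acc - 1) / rate_hz, method = "pd"),
            class = "CycleMarks")
}

#' @export
print.CycleMarks <- function(x, ...) {
  cat(sprintf("<CycleMarks> %d anchors (%s)\n", length(x$times_s), x$method))
  invisible(x)
}

#' Local cyclicity estimation on the normalized GZ channel
#'
#' Slides a window over the signal and scores, for each candidate period
#' between `1/f_max` and `1/f_min`, the normalized autocorrelation at that
#' lag. Regions whose best score exceeds half the noise threshold are deemed
#' locally cyclic; within them, anchors are placed at the local GZ maxima
#' (one per period, via distance-constrained peak picking at 70% of the
#' estimated local period). White noise produces no anchors at the default
#' threshold.
#'
#' @param gz_norm Numeric vector, max-abs normalized GZ.
#' @param rate_hz Sampling rate.
#' @param noise_threshold Cyclicity acceptance multiplier (default 1.0, i.e.,
#'   a normalized autocorrelation of at least 0.5).
#' @param f_min,f_max Candidate cycle frequency range in Hz.
#' @param t0_s Time of the first sample.
#' @return List of class `CycleMarks`: `times_s`, `method = "lce"`,
#'   `period_s` (median accepted period).
#' @export
detect_lce <- function(gz_norm, rate_hz, noise_threshold = 1.0,
                       f_min = 0.5, f_max = 6.0, t0_s = 0) {
  n <- length(gz_norm)
  if (n < 2 * rate_hz / f_min) stop("signal too short for f_min")
  if (max(abs(gz_norm)) > 1 + 1e-8) {
    stop("input must be max-abs normalized (|x| <= 1)")
  }
  lags <- unique(round(rate_hz / exp(seq(log(f_max), log(f_min), length.out = 40))))
  lags <- lags[lags >= 2 & lags < n / 2]
  step <- max(1L, round(0.25 * rate_hz))
  centers <- seq(1L, n, by = step)
  accept <- rep(FALSE, n)
  periods <- rep(NA_real_, length(centers))
  for (ci in seq_along(centers)) {
    c0 <- centers[ci]
    best <- -Inf; best_lag <- NA_integer_
    for (lag in lags) {
      half <- 2L * lag  # window of four periods: stable correlation length
      i0 <- max(1L, c0 - half); i1 <- min(n, c0 + half)
      if (i1 - i0 + 1 < 3 * lag) next
      a <- gz_norm[i0:(i1 - lag)]
      b <- gz_norm[(i0 + lag):i1]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(a, b)
      if (r > best) { best <- r; best_lag <- lag }
    }
    if (is.finite(best) && best >= 0.5 * noise_threshold) {
      i0 <- max(1L, c0 - step %/% 2); i1 <- min(n, c0 + step %/% 2)
      accept[i0:i1] <- TRUE
      periods[ci] <- best_lag / rate_hz
    }
  }
  if (!any(accept)) {
    return(structure(list(times_s = numeric(0), method = "lce",
                          period_s = NA_real_), class = "CycleMarks"))
  }
  period <- stats::median(periods, na.rm = TRUE)
  # peak picking restricted to accepted (locally cyclic) samples
  masked <- ifelse(accept, gz_norm, -Inf)
  pk <- detect_pd(pmin(pmax(masked, -1), 1), rate_hz,
                  min_distance_s = 0.7 * period,
                  min_height = 0.3, t0_s = t0_s)
  structure(list(times_s = pk$times_s, method = "lce", period_s = period),
            class = "CycleMarks")
}

#' Convert cycle anchors to a whole-cycle LabelTrack
#'
#' Consecutive anchors inside the same active (non-rest) region span one
#' cycle segment with phase `none`. Anchors inside rest are dropped.
#'
#' @param marks A `CycleMarks`.
#' @param rest Logical rest mask sampled at `rest_rate_hz`.
#' @param rest_rate_hz Sampling rate of the rest mask.
#' @param task Task-window row naming the cycle activity.
#' @param foot Foot label.
#' @return A `LabelTrack` of `cycle` segments.
#' @export
marks_to_track <- function(marks, rest, rest_rate_hz, task, foot = "left") {
  act <- setdiff(task$allowed_activities[[1]], c("rest", "sit"))
  if (length(act) != 1) stop("task must name exactly one cyclic activity")
  t <- marks$times_s
  t <- t[t >= task$start_s & t < task$end_s]
  if (length(t) > 0) {
    idx <- pmin(pmax(round(t * rest_rate_hz) + 1, 1), length(rest))
    t <- t[!rest[idx]]
  }
  if (length(t) < 2) return(label_track(NULL, foot = foot))
  # split where a gap covers rest (anchors in different active regions)
  gaps <- diff(t)
  ok <- gaps <= 2.5 * stats::median(gaps)
  segs <- segments(t[-length(t)][ok], t[-1][ok], act, "none")
  label_track(segs, foot = foot)
}
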