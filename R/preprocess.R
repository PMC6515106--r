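## Normalization, rest detection and insole-to-IMU synchronization.

#' Max-abs normalization of one channel
#'
#' Scales the named channel so that its maximum absolute value is 1 (the
#' scaling the peak-detection height threshold of 0.5 is defined against).
#'
#' @param series A `TimeSeries`.
#' @param channel Channel name or index.
#' @return `TimeSeries` with that channel rescaled.
#' @export
normalize_maxabs <- function(series, channel) {
  x <- ts_channel(series, channel)
  m <- max(abs(x))
  if (m == 0) stop("cannot max-abs normalize an all-zero channel")
  out <- series
  out$samples[, channel] <- x / m
  out
}

#' Per-person feature normalization (z-score)
#'
#' Normalizes each feature column to zero mean and unit standard deviation
#' over a subject's full recording, minimizing inter-person scale
#' differences. Zero-variance columns are set to 0 with a warning.
#'
#' @param features Numeric matrix (frames x features).
#' @return Matrix of the same shape.
#' @export
normalize_per_person <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 frames to normalize")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature column(s) set to 0")
    sdv[zero] <- 1
  }
  out <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  out[, zero] <- 0
  out
}

#' Energy-based rest mask
#'
#' Marks frames whose windowed mean squared motion energy falls below a
#' threshold as rest/sitting. Energy is the sum over motion channels of the
#' squared, mean-removed, max-abs-normalized signal, averaged over a centered
#' window.
#'
#' @param series A `TimeSeries` (typically GZ + AX of the shoe IMU).
#' @param window_s Smoothing window length in seconds.
#' @param threshold Energy threshold; larger thresholds mark more frames as
#'   rest (monotone).
#' @param channels Channels to use; defaults to all.
#' @return Logical vector, one entry per frame (`TRUE` = rest).
#' @export
rest_mask <- function(series, window_s = 0.300, threshold = 0.016,
                      channels = NULL) {
  stopifnot(window_s > 0)
  x <- series$samples
  if (!is.null(channels)) x <- x[, channels, drop = FALSE]
  n <- nrow(x)
  if (n == 0) return(logical(0))
  energy <- rep(0, n)
  for (j in seq_len(ncol(x))) {
    v <- x[, j] - mean(x[, j])
    m <- max(abs(v))
    if (m > 0) v <- v / m
    energy <- energy + v^2
  }
  w <- max(1L, round(window_s * series$rate_hz))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) %/% 2L
  padded <- c(rep(energy[1], half), energy, rep(energy[n], half))
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
  sm <- sm[(half + 1):(half + n)]
  sm < threshold
}

#' Synchronize insole to shoe-IMU acceleration
#'
#' Finds the resampling ratio and time lag aligning the insole x-axis
#' acceleration with the shoe-mounted IMU's, assuming both sense the same
#' motion. Every ratio on the grid `seq(ratio_min, ratio_max, ratio_step)`
#' (default 1.4-3.3 at 0.001 resolution) is tried: the insole channel is
#' linearly resampled onto the IMU clock by that factor and the normalized
#' cross-correlation with the IMU channel is maximized over lags. The
#' (ratio, lag) with the highest correlation wins; exact ties go to the
#' smaller lag, then the smaller ratio.
#'
#' @param insole_ax `TimeSeries` (or numeric vector) of insole x-acceleration.
#' @param shoe_ax `TimeSeries` of shoe-IMU axial acceleration (reference
#'   clock and rate).
#' @param ratio_min,ratio_max,ratio_step Resampling-factor search grid.
#' @param max_lag_s Largest lag magnitude searched, in seconds.
#' @return List with fields `ratio`, `lag_s`, `score` (class `SyncEstimate`).
#' @export
sync_insole_imu <- function(insole_ax, shoe_ax, ratio_min = 1.4,
                            ratio_max = 3.3, ratio_step = 0.001,
                            max_lag_s = 2.0) {
  y <- if (inherits(insole_ax, "TimeSeries")) insole_ax$samples[, 1] else
    as.numeric(insole_ax)
  x <- if (inherits(shoe_ax, "TimeSeries")) shoe_ax$samples[, 1] else
    as.numeric(shoe_ax)
  rate <- if (inherits(shoe_ax, "TimeSeries")) shoe_ax$rate_hz else
    stop("shoe_ax must be a TimeSeries (defines the reference clock)")
  if (length(x) == 0 || length(y) == 0) stop("empty input signal")
  x <- x - mean(x); y <- y - mean(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate (constant) signal; cannot synchronize")
  }
  ratios <- seq(ratio_min, ratio_max, by = ratio_step)
  max_lag <- round(max_lag_s * rate)
  # resampled insole samples beyond the shoe series + lag range cannot
  # overlap it, so the transform length only needs to cover that span
  keep_len <- length(x) + max_lag
  nfft <- 2^ceiling(log2(keep_len + max_lag + 1))
  fx <- Conj(fft(c(x, rep(0, nfft - length(x)))))
  nx2 <- sum(x^2)
  best <- list(score = -Inf, ratio = NA_real_, lag_s = NA_real_)
  lag_idx_pos <- seq_len(max_lag + 1)               # lags 0..max_lag
  lag_idx_neg <- seq(nfft - max_lag + 1, nfft)      # lags -max_lag..-1
  lags <- c(seq(-max_lag, -1), 0:max_lag)           # ascending order
  for (r in ratios) {
    m <- min(floor((length(y) - 1) * r) + 1, keep_len)
    # linear interpolation of y onto the IMU sample grid (stretch by r)
    pos <- (seq_len(m) - 1) / r
    i0 <- pmin(floor(pos), length(y) - 2)
    fr <- pos - i0
    yr <- y[i0 + 1] * (1 - fr) + y[i0 + 2] * fr
    fy <- fft(c(yr, rep(0, nfft - m)))
    cc <- Re(fft(fy * fx, inverse = TRUE)) / nfft
    # cc[l+1] = sum_t yr[t + l] x[t]; insole delayed by d samples peaks at l = d
    score <- c(cc[lag_idx_neg], cc[lag_idx_pos]) / sqrt(nx2 * sum(yr^2))
    k <- which.max(score)                            # first max = smaller lag
    if (score[k] > best$score + 1e-12) {
      best <- list(score = score[k], ratio = r, lag_s = lags[k] / rate)
    }
  }
  structure(best[c("ratio", "lag_s", "score")], class = "SyncEstimate")
}

#' @export
print.SyncEstimate <- function(x, ...) {
  cat(sprintf("<SyncEstimate> ratio = %.3f, lag = %.4f s, score = %.4f\n",
              x$ratio, x$lag_s, x$score))
  invisible(x)
}
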