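## Windowed features for the hHMM: per channel and window, the (population)
## variance, the three coefficients of a least-squares quadratic fit over
## window-local time, and the raw sample at the window center.

#' Extract windowed features from one or more channels
#'
#' Slides a window of `window_s` seconds in steps of `step_s` over the
#' signal. Per window and channel, five features: variance; the quadratic,
#' linear and constant coefficients of the second-order polynomial fit over
#' window-local time (centered at the window middle for conditioning); and
#' the raw sample at the window center (the earlier of the two middle samples
#' for even window lengths). Edge windows shorter than `window_s` are
#' dropped.
#'
#' @param series A `TimeSeries`; all channels are used.
#' @param window_s Window length in seconds (default 70 ms).
#' @param step_s Step size in seconds (default 5 ms).
#' @return List of class `FeatureMatrix`: `frames` (steps x 5*n_channels),
#'   `frame_times_s` (window centers), `window_s`, `step_s`.
#' @export
extract_features <- function(series, window_s = 0.070, step_s = 0.005) {
  rate <- series$rate_hz
  stopifnot(window_s >= 2 / rate, step_s >= 1 / rate)
  wlen <- max(2L, round(window_s * rate))
  step <- max(1L, round(step_s * rate))
  n <- nrow(series$samples)
  if (wlen > n) stop("window longer than the signal")
  starts <- seq(1L, n - wlen + 1L, by = step)
  tloc <- ((seq_len(wlen) - 1) - (wlen - 1) / 2) / rate  # window-local time
  # least-squares operator for [t^2, t, 1] over the fixed window grid
  X <- cbind(tloc^2, tloc, 1)
  Pinv <- solve(crossprod(X), t(X))
  ctr <- (wlen + 1L) %/% 2L  # earlier middle sample for even windows
  nch <- ncol(series$samples)
  out <- matrix(NA_real_, length(starts), 5L * nch)
  cn <- character(5L * nch)
  idx <- outer(seq_len(wlen) - 1L, starts, "+")  # wlen x nframes indices
  for (ch in seq_len(nch)) {
    w <- matrix(series$samples[idx, ch], nrow = wlen)  # windows as columns
    mu <- colMeans(w)
    v <- colMeans(w^2) - mu^2              # population variance
    coefs <- Pinv %*% w                    # 3 x nframes
    col0 <- (ch - 1L) * 5L
    out[, col0 + 1L] <- v
    out[, col0 + 2L] <- coefs[1, ]
    out[, col0 + 3L] <- coefs[2, ]
    out[, col0 + 4L] <- coefs[3, ]
    out[, col0 + 5L] <- w[ctr, ]
    nm <- colnames(series$samples)[ch]
    cn[col0 + 1:5] <- paste0(nm, "_", c("var", "poly2", "poly1", "poly0", "raw"))
  }
  colnames(out) <- cn
  centers <- series$t0_s + (starts - 1 + (wlen - 1) / 2) / rate
  structure(list(frames = out, frame_times_s = centers,
                 window_s = wlen / rate, step_s = step / rate),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix> %d frames x %d features (window %g ms, step %g ms)\n",
              nrow(x$frames), ncol(x$frames), 1000 * x$window_s,
              1000 * x$step_s))
  invisible(x)
}

#' Per-foot feature extraction
#'
#' Extracts features independently per foot from the GZ and AX channels of
#' each shoe IMU and applies per-person z-score normalization over the full
#' recording. Missing feet yield a single-foot result with a warning.
#'
#' @param subject Subject bundle with `imu_left` / `imu_right` `TimeSeries`.
#' @param window_s,step_s Windowing parameters.
#' @return Named list of `FeatureMatrix` (elements `left`, `right`).
#' @export
features_per_foot <- function(subject, window_s = 0.070, step_s = 0.005) {
  out <- list()
  for (foot in c("left", "right")) {
    imu <- subject[[paste0("imu_", foot)]]
    if (is.null(imu)) {
      warning("missing ", foot, " foot; producing single-foot features")
      next
    }
    fm <- extract_features(imu, window_s, step_s)
    fm$frames <- normalize_per_person(fm$frames)
    out[[foot]] <- fm
  }
  out
}
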