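## Zero-phase Butterworth low-pass. Coefficients come from the classical
## analog prototype + bilinear transform; forward-backward application with
## odd reflection padding removes phase distortion. DC gain is exactly 1.

butter_lowpass <- function(order, cutoff_hz, rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop("cutoff_hz must lie in (0, rate_hz/2)")
  }
  wc <- tan(pi * cutoff_hz / rate_hz)  # prewarped analog cutoff
  k <- seq_len(order)
  # left-half-plane Butterworth poles on the unit circle, scaled to cutoff
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p <- wc * complex(real = cos(theta), imaginary = sin(theta))
  # bilinear transform; n zeros at z = -1
  zp <- (1 + p) / (1 - p)
  gain <- Re(wc^order / prod(1 - p))
  a <- Re(poly_from_roots(zp))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  # enforce exact unit DC gain against rounding
  b <- b * (sum(a) / sum(b))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# Direct-form IIR filter via the stats::filter convolution/recursive split.
iir_filter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  z <- stats::filter(xp, b, method = "convolution", sides = 1)
  z <- as.numeric(z)[nb:(nb - 1 + n)]
  if (length(a) > 1) {
    z <- as.numeric(stats::filter(z, -a[-1] / a[1], method = "recursive"))
  }
  z / a[1]
}

filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1, 3 * (max(length(a), length(b)) - 1) * 4)
  if (npad < 1) return(x)
  # odd reflection keeps edge levels continuous
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  xe <- c(front, x, back)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase low-pass filter
#'
#' Applies a Butterworth low-pass (default 4th order) forward and backward to
#' every channel, giving zero phase shift and unit DC gain.
#'
#' @param series A `TimeSeries`.
#' @param cutoff_hz Cutoff frequency, must lie in `(0, rate_hz/2)`.
#' @param order Filter order (of the one-way filter).
#' @return Filtered `TimeSeries` with the same shape.
#' @export
lowpass <- function(series, cutoff_hz, order = 4) {
  stopifnot(inherits(series, "TimeSeries"))
  ba <- butter_lowpass(order, cutoff_hz, series$rate_hz)
  out <- series
  if (nrow(series$samples) > 0) {
    out$samples <- apply(series$samples, 2, function(x) filtfilt_ba(ba$b, ba$a, x))
    if (is.null(dim(out$samples))) {
      out$samples <- matrix(out$samples, ncol = ncol(series$samples))
    }
    colnames(out$samples) <- colnames(series$samples)
  }
  out
}
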