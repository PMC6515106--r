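test_that("max-abs normalization scales and is idempotent", {
  ts <- time_series(cbind(x = c(0, 2, -4)), 100)
  out <- normalize_maxabs(ts, "x")
  expect_equal(ts_channel(out, "x"), c(0, 0.5, -1))
  expect_equal(normalize_maxabs(out, "x")$samples, out$samples)
  expect_error(normalize_maxabs(time_series(cbind(x = c(0, 0)), 10), "x"),
               "all-zero")
  # property: unit max-abs after the call, any input
  set.seed(1)
  for (i in 1:100) {
    v <- rnorm(50) * 10^runif(1, -3, 3)
    r <- normalize_maxabs(time_series(cbind(x = v), 100), "x")
    expect_equal(max(abs(ts_channel(r, "x"))), 1)
  }
})

test_that("per-person normalization z-scores and handles constants", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 30))
  z <- normalize_per_person(m)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_warning(z2 <- normalize_per_person(cbind(a = 1:3, b = rep(5, 3))),
                 "zero-variance")
  expect_equal(z2[, "b"], rep(0, 3))
  # two subjects differing only in scale normalize to the same distribution
  set.seed(2)
  base <- rnorm(2000)
  z_a <- normalize_per_person(matrix(base, ncol = 1))
  z_b <- normalize_per_person(matrix(10 * base + 5, ncol = 1))
  expect_equal(z_a, z_b, tolerance = 1e-10)
})

test_that("rest mask detects low-energy spans and is monotone in threshold", {
  expect_true(all(rest_mask(time_series(cbind(GZ = rep(0, 200),
                                              AX = rep(0, 200)), 200))))
  t <- seq(0, 2, by = 1 / 200)
  loud <- time_series(cbind(GZ = sin(2 * pi * 3 * t), AX = cos(2 * pi * 3 * t)),
                      200)
  m <- rest_mask(loud, threshold = 0.05)
  expect_false(any(m[40:(length(t) - 40)]))
  # monotone: larger threshold => superset of rest frames
  sub <- generate_subject(subject_scenario(seed = 21))
  m1 <- rest_mask(sub$imu_left, threshold = 0.01)
  m2 <- rest_mask(sub$imu_left, threshold = 0.05)
  expect_true(all(m2[m1]))
  # agreement with the true rest segments at the default threshold
  truth_rest <- rep(TRUE, nrow(sub$imu_left$samples))
  tt <- ts_times(sub$imu_left)
  segs <- sub$truth$left$segments
  for (i in seq_len(nrow(segs))) {
    truth_rest[tt >= segs$start_s[i] & tt < segs$end_s[i]] <- FALSE
  }
  # a swing-borne foot is moving during stance phases too (bout != rest)
  m <- rest_mask(sub$imu_left)
  expect_gt(mean(m == truth_rest), 0.9)
})

test_that("lowpass has unit DC gain, attenuates stopband, smooths noise", {
  const <- time_series(cbind(x = rep(3.5, 300)), 100)
  expect_equal(ts_channel(lowpass(const, 15), "x"), rep(3.5, 300),
               tolerance = 1e-8)
  t <- seq(0, 3, by = 0.01)
  s40 <- time_series(cbind(x = sin(2 * pi * 40 * t)), 100)
  out <- ts_channel(lowpass(s40, 15), "x")
  expect_lt(max(abs(out[50:250])), 0.1)  # > 90% attenuation
  set.seed(3)
  wn <- time_series(cbind(x = rnorm(2000)), 100)
  expect_lt(var(ts_channel(lowpass(wn, 15), "x")), var(ts_channel(wn, "x")))
  expect_error(lowpass(wn, 60), "cutoff")
})

test_that("insole synchronization recovers known transforms", {
  rate <- 200
  set.seed(4)
  # smooth band-limited latent signal
  t <- seq(0, 4, by = 1 / rate)
  latent <- sin(2 * pi * 1.3 * t) + 0.6 * sin(2 * pi * 3.7 * t + 1) +
    0.3 * sin(2 * pi * 7.1 * t + 2)
  shoe <- time_series(cbind(ax = latent), rate)
  make_insole <- function(r, lag) {
    m <- floor(length(t) / r)
    tk <- (seq_len(m) - 1) * r / rate - lag
    approx(t, latent, xout = tk, rule = 2)$y
  }
  est <- sync_insole_imu(make_insole(2.0, 0.35), shoe)
  expect_equal(est$ratio, 2.0, tolerance = 0.0011 / 2)
  expect_equal(est$lag_s, 0.35, tolerance = 1.5 / rate)
  est0 <- sync_insole_imu(make_insole(2.0, 0), shoe)
  expect_equal(est0$lag_s, 0, tolerance = 1.5 / rate)
  # 10% additive noise on both sides
  noisy_shoe <- time_series(cbind(ax = latent + rnorm(length(t), sd = 0.1)),
                            rate)
  ins <- make_insole(2.4, 0.2)
  est_n <- sync_insole_imu(ins + rnorm(length(ins), sd = 0.1), noisy_shoe)
  expect_equal(est_n$ratio, 2.4, tolerance = 0.0011 / 2.4)
  expect_equal(est_n$lag_s, 0.2, tolerance = 1.5 / rate)
  expect_error(sync_insole_imu(rep(1, 100), shoe), "degenerate")
})
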