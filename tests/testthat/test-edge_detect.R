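test_that("a single smoothed step yields one rising event at the steepest point", {
  # raised-cosine ramp over 12 samples: derivative has a unique analytic
  # maximum at the ramp center
  ramp <- (1 - cos(pi * (0:11) / 11)) / 2
  x <- c(rep(0, 50), ramp, rep(1, 50))
  ts <- time_series(cbind(p1 = x), 100)
  ev <- detect_channel_edges(ts, 1, min_strength = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$polarity, "rising")
  center <- (50 + 5.5) / 100  # middle of the 12-sample ramp
  expect_lt(abs(ev$time_s - center), 1.5 / 100)
})

test_that("constant signals and unnormalized inputs are handled", {
  flat <- time_series(cbind(p1 = rep(0, 100)), 100)
  expect_equal(nrow(detect_channel_edges(flat, 1)), 0)
  bad <- time_series(cbind(p1 = c(rep(0, 10), rep(5, 10))), 100)
  expect_error(detect_channel_edges(bad, 1), "normalized")
})

test_that("a 5-cycle square wave with ramps yields 5 rising + 5 falling", {
  one <- c(seq(0, 1, length.out = 6), rep(1, 30), seq(1, 0, length.out = 6),
           rep(0, 30))
  x <- c(rep(0, 20), rep(one, 5), rep(0, 20))
  # filtering is part of the detector precondition; it also removes the
  # floating-point plateau ties of the raw ramp
  ts <- lowpass(time_series(cbind(p1 = x), 100), 15)
  ts$samples <- pmin(pmax(ts$samples, 0), 1)
  ev <- detect_channel_edges(ts, 1, min_strength = 5)
  expect_equal(sum(ev$polarity == "rising"), 5)
  expect_equal(sum(ev$polarity == "falling"), 5)
  # monotonicity: a higher threshold never yields more events
  for (th in c(5, 10, 15, 20)) {
    n_lo <- nrow(detect_channel_edges(ts, 1, th))
    n_hi <- nrow(detect_channel_edges(ts, 1, th + 5))
    expect_lte(n_hi, n_lo)
  }
})

test_that("edge aggregation applies the pairing rules", {
  ev <- function(t, pol, s = 10) {
    data.frame(time_s = t, polarity = pol, channel = 1L, strength = s)
  }
  # unpaired rising event is dropped
  expect_equal(nrow(aggregate_edges(ev(1, "rising"))), 0)
  # two rising events 50 ms apart then one falling: earliest rising kept
  e <- rbind(ev(1.00, "rising"), ev(1.05, "rising"), ev(1.50, "falling"))
  st <- aggregate_edges(e)
  expect_equal(nrow(st), 1)
  expect_equal(st$start_s, 1.00)
  expect_equal(st$end_s, 1.50)
  # same-polarity neighbors beyond the cluster: stronger one wins
  e2 <- rbind(ev(1.0, "rising", 5), ev(1.5, "rising", 20), ev(2.0, "falling"))
  st2 <- aggregate_edges(e2)
  expect_equal(st2$start_s, 1.5)
  # output intervals are disjoint and sorted
  set.seed(7)
  t <- sort(runif(40, 0, 20))
  pol <- sample(c("rising", "falling"), 40, replace = TRUE)
  st3 <- aggregate_edges(ev(t, pol, runif(40, 1, 30)))
  if (nrow(st3) > 1) {
    expect_true(all(st3$start_s[-1] > st3$end_s[-nrow(st3)]))
    expect_true(all(st3$end_s > st3$start_s))
  }
})

test_that("stance starts align with truth onsets on a synthetic walk bout", {
  sub <- generate_subject(subject_scenario(seed = 31, bouts = data.frame(
    activity = "walk", n_cycles = 12L, preceding_rest_s = 3)))
  cfg <- default_config()
  ins <- sub$insole_left
  pr <- time_series(ins$samples[, paste0("p", 1:5)], rate_hz = ins$rate_hz)
  pr <- normalize_pressure(lowpass(pr, cfg$lowpass$cutoff_hz))
  pr$samples <- pmin(pmax(pr$samples, 0), 1)
  evl <- lapply(1:5, function(j) detect_channel_edges(pr, j,
                                                      cfg$edges$min_strength))
  st <- aggregate_edges(evl)
  segs <- sub$truth$left$segments
  onsets <- segs$start_s[segs$phase == "stance"]
  hit <- vapply(onsets, function(o) any(abs(st$start_s - o) <= 0.03),
                logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("edges_to_track builds a compliant track and validates tasks", {
  sub <- generate_subject(subject_scenario(seed = 33))
  tr <- edge_detect_track(sub$insole_left, sub$imu_left, sub$tasks)
  expect_invisible(check_track_invariants(tr))
  multi <- task_windows(0, 10, "bad", list(c("walk", "jog")))
  expect_error(edges_to_track(data.frame(start_s = 1, end_s = 2),
                              rep(FALSE, 100), 10, multi),
               "exactly one cyclic")
})
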