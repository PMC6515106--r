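test_that("a single walk bout yields n swings and n-1 stances", {
  sc <- subject_scenario(seed = 3, bouts = data.frame(
    activity = "walk", n_cycles = 10L, preceding_rest_s = 3))
  sub <- generate_subject(sc)
  segs <- sub$truth$left$segments
  expect_equal(sum(segs$phase == "swing"), 10)
  expect_equal(sum(segs$phase == "stance"), 9)
  expect_invisible(check_track_invariants(sub$truth$left))
})

test_that("generation is deterministic per seed and sensitive to it", {
  a <- generate_subject(subject_scenario(seed = 5))
  b <- generate_subject(subject_scenario(seed = 5))
  expect_identical(a$imu_left$samples, b$imu_left$samples)
  expect_identical(a$truth$left$segments, b$truth$left$segments)
  c <- generate_subject(subject_scenario(seed = 6))
  expect_false(identical(a$truth$left$segments, c$truth$left$segments))

  b1 <- generate_batch(2, 1)
  b2 <- generate_batch(2, 1)
  expect_identical(b1[[1]]$imu_left$samples, b2[[1]]$imu_left$samples)
  b3 <- generate_batch(2, 2)
  expect_false(identical(
    b1[[1]]$truth$left$segments$start_s,
    b3[[1]]$truth$left$segments$start_s))
})

test_that("swing fraction of the truth matches the template", {
  tpl <- default_templates()
  tpl$swing_fraction[tpl$activity == "walk"] <- 0.4
  tpl$stride_time_cv[tpl$activity == "walk"] <- 0
  sc <- subject_scenario(seed = 1, bouts = data.frame(
    activity = "walk", n_cycles = 50L, preceding_rest_s = 2))
  sub <- generate_subject(sc, templates = tpl)
  segs <- sub$truth$left$segments
  sw <- segs[segs$phase == "swing", ]
  strides <- diff(sw$start_s)
  ratio <- mean((sw$end_s - sw$start_s)[-nrow(sw)] / strides)
  expect_equal(ratio, 0.40, tolerance = 0.01 / 0.40)
})

test_that("unknown bout activities are rejected and batches validate", {
  expect_error(generate_subject(subject_scenario(
    seed = 1, bouts = data.frame(activity = "moonwalk", n_cycles = 3,
                                 preceding_rest_s = 1))), "unknown activity")
  expect_error(generate_batch(0, 1), "n_subjects")
  batch <- generate_batch(4, 7)
  for (sub in batch) {
    expect_invisible(check_track_invariants(sub$truth$left))
    expect_invisible(check_track_invariants(sub$truth$right))
  }
})

test_that("pressure is loaded in stance and unloaded in swing", {
  sub <- generate_subject(subject_scenario(seed = 11))
  for (foot in c("left", "right")) {
    ins <- sub[[paste0("insole_", foot)]]
    psum <- rowSums(ins$samples[, paste0("p", 1:5)])
    tp <- ts_times(ins)
    segs <- sub$truth[[foot]]$segments
    thr <- 0.5 * max(psum)
    frac_ok <- function(ph, below) {
      s <- segs[segs$phase == ph, ]
      sel <- rep(FALSE, length(tp))
      for (i in seq_len(nrow(s))) {
        # interior samples only: transitions ramp over ~50 ms
        sel <- sel | (tp >= s$start_s[i] + 0.08 & tp < s$end_s[i] - 0.08)
      }
      if (below) mean(psum[sel] < thr) else mean(psum[sel] >= thr)
    }
    expect_gt(frac_ok("swing", TRUE), 0.9)
    expect_gt(frac_ok("stance", FALSE), 0.9)
  }
})

test_that("each swing contains one dominant GZ peak; spectrum matches stride", {
  sc <- subject_scenario(seed = 13, bouts = data.frame(
    activity = "jog", n_cycles = 20L, preceding_rest_s = 2), noise_sd = 0.05)
  sub <- generate_subject(sc)
  gz <- ts_channel(sub$imu_left, "GZ")
  tt <- ts_times(sub$imu_left)
  segs <- sub$truth$left$segments
  sw <- segs[segs$phase == "swing", ]
  gmax <- max(gz)
  for (i in seq_len(nrow(sw))) {
    v <- gz[tt >= sw$start_s[i] & tt < sw$end_s[i]]
    expect_gt(max(v), 0.5 * gmax)
  }
  # dominant frequency of the steady bout ~ 1/stride_time within 10%
  bout <- gz[tt >= min(segs$start_s) & tt <= max(segs$end_s)]
  sp <- Mod(fft(bout - mean(bout)))^2
  freqs <- (seq_along(bout) - 1) * 200 / length(bout)
  keep <- freqs > 0.3 & freqs < 6
  fdom <- freqs[keep][which.max(sp[keep])]
  stride <- mean(diff(sw$start_s))
  expect_equal(fdom, 1 / stride, tolerance = 0.1)
})

test_that("insole accelerometer is the resampled, delayed latent signal", {
  sc <- subject_scenario(seed = 17, insole_ratio = 2.0, insole_lag_s = 0.35,
                         noise_sd = 0)
  sub <- generate_subject(sc)
  acc <- attr(sub$insole_left, "insole_accel")
  ax <- ts_channel(sub$imu_left, "AX")
  # sample k of the insole should equal latent at k*ratio/200 - lag
  k <- 300:320
  tk <- (k - 1) * 2.0 / 200 - 0.35
  latent <- approx(ts_times(sub$imu_left), ax, xout = tk, rule = 2)$y
  expect_equal(ts_channel(acc, "ax")[k], latent, tolerance = 1e-6)
})
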