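## Synthetic per-foot recordings: shoe IMU (GZ, AX @ 200 Hz), 5-channel
## pressure insole (@ 100 Hz) with an insole accelerometer on a distorted
## clock, plus ground-truth label tracks and protocol task windows.
##
## Waveforms are deliberately minimal: a raised-cosine GZ pulse peaking at
## mid-swing, an AX impact transient at each ground contact, and staggered
## heel-to-toe pressure ramps whenever the foot is on the ground (stance and
## standing rest alike; only swing unloads the insole).

#' Default activity templates
#'
#' One row per supported activity: typical stride time, stride-time
#' coefficient of variation, swing fraction of the stride, GZ peak amplitude
#' (rad/s-like arbitrary units) and relative insole load. Stride times
#' decrease from walking through jogging to running; swing fractions sit near
#' 40% for walking/stairs/hopping and near 60% for skipping, side-stepping
#' and jumping, matching typical self-paced movement.
#'
#' @return data.frame of templates keyed by `activity`.
#' @export
default_templates <- function() {
  data.frame(
    activity       = c("walk", "jog", "run", "stairs", "jump", "hop",
                       "skip", "side_step", "run_on_spot", "cycle"),
    stride_time_s  = c(1.10, 0.80, 0.70, 1.15, 0.60, 0.70,
                       0.55, 0.70, 0.60, 1.00),
    stride_time_cv = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                       0.05, 0.05, 0.05, 0.03),
    swing_fraction = c(0.40, 0.45, 0.50, 0.40, 0.60, 0.40,
                       0.60, 0.60, 0.45, 0.50),
    gz_peak_amp    = c(1.00, 1.50, 2.00, 0.80, 1.20, 1.10,
                       1.30, 0.90, 1.40, 1.00),
    pressure_load  = c(1.00, 1.20, 1.40, 1.00, 1.30, 1.20,
                       1.10, 1.00, 1.10, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Build a subject scenario
#'
#' @param seed Integer RNG seed for this subject.
#' @param bouts data.frame with columns `activity`, `n_cycles`,
#'   `preceding_rest_s`; defaults to one walk, jog and run bout of 8 cycles
#'   separated by 3 s of standing rest.
#' @param noise_sd Additive Gaussian noise sd on all channels, relative to a
#'   unit GZ peak (default 0.1: clearly visible but not crippling).
#' @param insole_ratio True insole resampling factor in `[1.4, 3.3]`
#'   (hardware clocks sit near 2.0).
#' @param insole_lag_s True insole-to-IMU delay in seconds.
#' @param trailing_rest_s Standing rest appended after the last bout.
#' @return List of class `SubjectScenario`.
#' @export
subject_scenario <- function(seed = 1,
                             bouts = data.frame(
                               activity = c("walk", "jog", "run"),
                               n_cycles = c(8L, 8L, 8L),
                               preceding_rest_s = c(3, 3, 3)),
                             noise_sd = 0.1, insole_ratio = 2.0,
                             insole_lag_s = 0.3, trailing_rest_s = 2) {
  stopifnot(all(bouts$n_cycles >= 1))
  if (insole_ratio < 1.4 || insole_ratio > 3.3) {
    stop("insole_ratio must lie in [1.4, 3.3] (the synchronizer search range)")
  }
  structure(list(seed = as.integer(seed), bouts = bouts, noise_sd = noise_sd,
                 insole_ratio = insole_ratio, insole_lag_s = insole_lag_s,
                 trailing_rest_s = trailing_rest_s),
            class = "SubjectScenario")
}

# Truth schedule for one foot. Bouts of cyclic activities hold n swings and
# n-1 stances (a bout starts at first lift-off and ends at final ground
# contact). Cycling bouts hold peak-to-peak whole-cycle segments.
schedule_foot <- function(scenario, templates, foot_offset_s) {
  segs <- list()
  anchors <- list()
  t <- 0
  for (b in seq_len(nrow(scenario$bouts))) {
    act <- scenario$bouts$activity[b]
    tpl <- templates[templates$activity == act, ]
    if (nrow(tpl) != 1) stop("no template for activity: ", act)
    n <- scenario$bouts$n_cycles[b]
    t <- t + scenario$bouts$preceding_rest_s[b] + foot_offset_s
    strides <- tpl$stride_time_s *
      pmax(0.4, 1 + tpl$stride_time_cv * stats::rnorm(n))
    if (act == "cycle") {
      peaks <- t + cumsum(strides) - strides / 2
      anchors[[length(anchors) + 1]] <- peaks
      if (n >= 2) {
        segs[[length(segs) + 1]] <- segments(
          peaks[-n], peaks[-1], act, "none")
      }
      t <- t + sum(strides)
    } else {
      sw <- tpl$swing_fraction * strides
      starts <- t + c(0, cumsum(strides[-n]))
      seg_start <- c(rbind(starts, starts + sw))[-2 * n]
      seg_end <- c(rbind(starts + sw, starts + strides))[-2 * n]
      segs[[length(segs) + 1]] <- segments(
        seg_start, seg_end, act, rep(c("swing", "stance"), n)[-2 * n])
      t <- starts[n] + sw[n]   # bout ends at the final ground contact
    }
    t <- t - foot_offset_s
  }
  list(segments = do.call(rbind, segs), end_s = t + scenario$trailing_rest_s,
       anchors = anchors)
}

raised_cosine <- function(tt, start, dur) {
  u <- (tt - start) / dur
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

impact <- function(tt, t0, amp, f = 30, tau = 0.04) {
  u <- tt - t0
  ifelse(u >= 0 & u <= 0.2, amp * exp(-u / tau) * sin(2 * pi * f * u), 0)
}

# Ground-contact intervals (foot on insole) for one foot's schedule: the
# complement of swing segments over [0, end_s]. Cycling keeps light constant
# contact and is excluded from the unloaded set.
contact_intervals <- function(segs, end_s) {
  sw <- segs[segs$phase == "swing", , drop = FALSE]
  if (nrow(sw) == 0) return(data.frame(start = 0, end = end_s))
  start <- c(0, sw$end_s)
  end <- c(sw$start_s, end_s)
  keep <- end - start > 1e-9
  data.frame(start = start[keep], end = end[keep])
}

#' Generate one synthetic subject
#'
#' Produces per-foot shoe-IMU series (`GZ`, `AX` at 200 Hz), per-foot insole
#' series (pressure channels `p1`..`p5` at 100 Hz on the IMU-aligned clock
#' plus an `ax` channel on the distorted insole clock), ground-truth
#' `LabelTrack`s and protocol `TaskWindow`s. Deterministic given the scenario
#' seed.
#'
#' @param scenario A `SubjectScenario`.
#' @param templates Activity templates, see [default_templates()].
#' @param rate_imu_hz,rate_insole_hz Sampling rates.
#' @param foot_offset_frac Right-foot phase offset as a fraction of the first
#'   stride.
#' @return List with elements `imu_left`, `imu_right`, `insole_left`,
#'   `insole_right`, `truth` (list `left`/`right` of `LabelTrack`), `tasks`.
#' @export
generate_subject <- function(scenario, templates = default_templates(),
                             rate_imu_hz = 200, rate_insole_hz = 100,
                             foot_offset_frac = 0.5) {
  stopifnot(inherits(scenario, "SubjectScenario"))
  bad <- setdiff(scenario$bouts$activity, templates$activity)
  if (length(bad) > 0) stop("unknown activity in bouts: ",
                            paste(bad, collapse = ", "))
  set.seed(scenario$seed)
  out <- list()
  sched <- list()
  for (foot in c("left", "right")) {
    off <- if (foot == "right") {
      foot_offset_frac *
        templates$stride_time_s[match(scenario$bouts$activity[1],
                                      templates$activity)]
    } else 0
    sched[[foot]] <- schedule_foot(scenario, templates, off)
  }
  end_s <- max(sched$left$end_s, sched$right$end_s)
  nt <- round(end_s * rate_imu_hz)
  tt <- (seq_len(nt) - 1) / rate_imu_hz

  truth <- list()
  for (foot in c("left", "right")) {
    segs <- sched[[foot]]$segments
    truth[[foot]] <- label_track(segs, foot = foot)

    gz <- rep(0, nt)
    ax <- rep(1, nt)  # gravity baseline, arbitrary units
    for (i in seq_len(nrow(segs))) {
      tpl <- templates[templates$activity == segs$activity[i], ]
      if (segs$phase[i] == "swing") {
        dur <- segs$end_s[i] - segs$start_s[i]
        gz <- gz + tpl$gz_peak_amp *
          raised_cosine(tt, segs$start_s[i], dur)
        # impact at ground contact ending the swing
        ax <- ax + impact(tt, segs$end_s[i], 1.5 * tpl$pressure_load)
        ax <- ax + impact(tt, segs$start_s[i], -0.5 * tpl$pressure_load)
      } else if (segs$phase[i] == "stance") {
        # heel-to-toe roll-over: slower negative sagittal rotation, keeps
        # stance distinguishable from standing rest
        dur <- segs$end_s[i] - segs$start_s[i]
        gz <- gz - 0.35 * tpl$gz_peak_amp *
          raised_cosine(tt, segs$start_s[i], dur)
      }
    }
    # cycling bouts: one raised-cosine GZ pulse per pedal cycle, peaking at
    # each anchor time
    if (length(sched[[foot]]$anchors) > 0) {
      amp_c <- templates$gz_peak_amp[templates$activity == "cycle"]
      for (anc in sched[[foot]]$anchors) {
        dur <- if (length(anc) >= 2) stats::median(diff(anc)) else 1
        # knee-flexion-like pulse spanning half the pedal cycle
        for (a in anc) {
          gz <- gz + amp_c * raised_cosine(tt, a - dur / 4, dur / 2)
        }
      }
    }
    ax_clean <- ax
    gz <- gz + stats::rnorm(nt, sd = scenario$noise_sd)
    ax <- ax + stats::rnorm(nt, sd = scenario$noise_sd)
    imu <- time_series(cbind(GZ = gz, AX = ax), rate_hz = rate_imu_hz)

    # pressure on the IMU-aligned clock, 5 staggered channels
    np <- round(end_s * rate_insole_hz)
    tp <- (seq_len(np) - 1) / rate_insole_hz
    contacts <- contact_intervals(segs, end_s)
    press <- matrix(0, np, 5)
    ramp_s <- 0.03
    stagger <- 0.01
    for (ci in seq_len(nrow(contacts))) {
      cs <- contacts$start[ci]; ce <- contacts$end[ci]
      for (ch in 1:5) {
        on0 <- cs + stagger * (ch - 1)           # heel loads first
        off1 <- ce - stagger * (5 - ch)          # toe unloads last
        up <- pmin(pmax((tp - on0) / ramp_s, 0), 1)
        down <- pmin(pmax((off1 - tp) / ramp_s, 0), 1)
        press[, ch] <- press[, ch] + pmin(up, down)
      }
    }
    # cycling: light constant contact already covered (no swings there)
    press <- press + matrix(stats::rnorm(np * 5, sd = 0.05 * scenario$noise_sd + 1e-4),
                            np, 5)

    # insole accelerometer: latent = clean AX, resampled by the true ratio
    # and delayed; independent noise
    r <- scenario$insole_ratio
    m <- floor((nt - 1) / r) + 1
    t_ins <- (seq_len(m) - 1) * r / rate_imu_hz - scenario$insole_lag_s
    ins_ax <- stats::approx(tt, ax_clean, xout = t_ins, rule = 2)$y +
      stats::rnorm(m, sd = scenario$noise_sd)
    insole <- time_series(cbind(press, c(ins_ax, rep(0, max(0, np - m)))[seq_len(np)]),
                          rate_hz = rate_insole_hz,
                          channel_names = c(paste0("p", 1:5), "ax"))
    # keep the full-length distorted accel separately (it has its own clock)
    attr(insole, "insole_accel") <- time_series(ins_ax, rate_hz = rate_insole_hz,
                                                channel_names = "ax")
    out[[paste0("imu_", foot)]] <- imu
    out[[paste0("insole_", foot)]] <- insole
  }
  out$truth <- truth

  # task windows: one per bout, split midway through the separating rest
  lsegs <- sched$left$segments
  b <- bouts_of(label_track(lsegs, "left"))
  bs <- lsegs$start_s[b$first]
  be <- lsegs$end_s[b$last]
  cuts <- c(0, (be[-length(be)] + bs[-1]) / 2, end_s)
  out$tasks <- task_windows(cuts[-length(cuts)], cuts[-1],
                            paste0(b$activity, "_", seq_along(bs)),
                            lapply(b$activity, function(a) c(a, "rest")))
  out$scenario <- scenario
  out
}

#' Generate a batch of synthetic subjects
#'
#' Subjects differ in their per-subject template jitter (stride time scaled
#' by up to +/-10%, swing fraction by +/-0.03, amplitudes by +/-15%),
#' emulating inter-subject variety of motion styles. Deterministic per
#' `(n_subjects, seed)`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param scenario Base `SubjectScenario` (per-subject seeds are derived).
#' @param templates Base templates to jitter.
#' @return List of subject bundles as returned by [generate_subject()].
#' @export
generate_batch <- function(n_subjects, seed, scenario = subject_scenario(),
                           templates = default_templates()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, n_subjects)
  jit <- lapply(seq_len(n_subjects), function(i) {
    list(stride = stats::runif(1, 0.9, 1.1),
         swing = stats::runif(1, -0.03, 0.03),
         amp = stats::runif(1, 0.85, 1.15))
  })
  lapply(seq_len(n_subjects), function(i) {
    tpl <- templates
    tpl$stride_time_s <- tpl$stride_time_s * jit[[i]]$stride
    tpl$swing_fraction <- pmin(0.75, pmax(0.25,
                                          tpl$swing_fraction + jit[[i]]$swing))
    tpl$gz_peak_amp <- tpl$gz_peak_amp * jit[[i]]$amp
    sc <- scenario
    sc$seed <- sub_seeds[i]
    generate_subject(sc, tpl)
  })
}
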