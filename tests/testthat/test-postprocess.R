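test_that("merge_consecutive joins equal-labeled neighbors and is idempotent", {
  tr <- label_track(segments(c(0, 0.3), c(0.3, 0.6), "walk", "swing"))
  m <- merge_consecutive(tr)
  expect_equal(m$segments$start_s, 0)
  expect_equal(m$segments$end_s, 0.6)
  expect_equal(merge_consecutive(m)$segments, m$segments)
  # split-then-merge round trip recovers the original
  set.seed(11)
  for (i in 1:20) {
    orig <- merge_consecutive(label_track(
      segments(c(0, 0.4, 0.7), c(0.4, 0.7, 1.3), "jog",
               c("swing", "stance", "swing"))))
    segs <- orig$segments
    split <- NULL
    for (k in seq_len(nrow(segs))) {
      cuts <- sort(runif(sample(0:3, 1), segs$start_s[k], segs$end_s[k]))
      b <- c(segs$start_s[k], cuts, segs$end_s[k])
      split <- rbind(split, segments(head(b, -1), b[-1], segs$activity[k],
                                     segs$phase[k]))
    }
    back <- merge_consecutive(label_track(split))
    expect_equal(back$segments, orig$segments, tolerance = 1e-12)
  }
})

test_that("swing-boundary rule trims offending stances and is idempotent", {
  tr <- label_track(segments(c(0, 0.4, 0.8, 1.2), c(0.4, 0.8, 1.2, 1.6),
                             "walk", c("stance", "swing", "stance", "swing")))
  out <- enforce_swing_boundaries(tr)
  expect_equal(out$segments$phase, c("swing", "stance", "swing"))
  expect_equal(out$segments$start_s[1], 0.4)
  expect_equal(enforce_swing_boundaries(out)$segments, out$segments)
  # compliant bout unchanged
  ok <- label_track(segments(c(0, 0.4, 0.8), c(0.4, 0.8, 1.2), "walk",
                             c("swing", "stance", "swing")))
  expect_equal(enforce_swing_boundaries(ok)$segments, ok$segments)
  # never increases labeled duration
  dur <- function(t) sum(t$segments$end_s - t$segments$start_s)
  expect_lte(dur(out), dur(tr))
})

test_that("a transition separator stance is exempt from the rule", {
  tr <- label_track(segments(
    c(0, 0.4, 0.8, 1.2), c(0.4, 0.8, 1.2, 1.6),
    c("walk", "walk", "walk", "jog"),
    c("swing", "stance", "swing", "swing")))
  # contiguous walk->jog with no separator: unchanged
  expect_equal(enforce_swing_boundaries(tr)$segments, tr$segments)
  sep <- label_track(segments(
    c(0, 0.4, 0.8, 1.2, 1.6), c(0.4, 0.8, 1.2, 1.6, 2.0),
    c("walk", "walk", "walk", "jog", "jog"),
    c("swing", "stance", "swing", "stance", "swing")))
  # the jog-leading stance at 1.2 directly follows the walk bout ->
  # transition separator, kept
  out <- enforce_swing_boundaries(sep)
  expect_true(any(out$segments$start_s == 1.2 & out$segments$phase == "stance"))
  expect_equal(nrow(out$segments), 5)
})

test_that("rules commute and produce invariant-passing tracks", {
  for (seed in 1:50) {
    tr <- random_perturbed_track(seed)
    a <- enforce_swing_boundaries(merge_consecutive(tr))
    b <- merge_consecutive(enforce_swing_boundaries(tr))
    twice <- enforce_swing_boundaries(merge_consecutive(a))
    expect_equal(a$segments, twice$segments)
    expect_equal(a$segments, merge_consecutive(b)$segments)
    expect_invisible(check_track_invariants(a))
  }
})

test_that("outlier flagging finds the constructed outlier and edge cases", {
  mk_track <- function(cyc_times) {
    t <- 0; segs <- NULL
    for (ct in cyc_times) {
      segs <- rbind(segs, segments(c(t, t + 0.4 * ct), c(t + 0.4 * ct, t + ct),
                                   "walk", c("swing", "stance")))
      t <- t + ct
    }
    # final swing so the bout is compliant
    segs <- rbind(segs, segments(t, t + 0.4, "walk", "swing"))
    label_track(segs)
  }
  uniform <- mk_track(rep(1, 50))
  expect_equal(nrow(flag_outliers(uniform, k = 3)), 0)
  # one double-duration cycle among 50 uniform ones
  outl <- mk_track(c(rep(1, 25), 2, rep(1, 25)))
  fl <- flag_outliers(outl, k = 3)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$start_s, 25)
  # k = 0: degenerate limit, everything flagged
  expect_equal(nrow(flag_outliers(uniform, k = 0)), 50)
  # too few cycles: warning, no flags
  small <- mk_track(rep(1, 3))
  expect_warning(f2 <- flag_outliers(small), "fewer than")
  expect_equal(nrow(f2), 0)
})
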