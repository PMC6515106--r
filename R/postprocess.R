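## Post-processing rules applied between prediction and manual correction,
## plus statistical outlier flagging of cycles.

#' Join consecutive equal-labeled segments
#'
#' Adjacent contiguous segments sharing the same activity and phase are
#' merged into one. Idempotent.
#'
#' @param track A `LabelTrack`.
#' @param tol_s Contiguity tolerance in seconds.
#' @return A `LabelTrack`.
#' @export
merge_consecutive <- function(track, tol_s = 1e-6) {
  segs <- track$segments
  n <- nrow(segs)
  if (n < 2) return(track)
  new_grp <- c(TRUE, segs$activity[-1] != segs$activity[-n] |
                 segs$phase[-1] != segs$phase[-n] |
                 segs$start_s[-1] > segs$end_s[-n] + tol_s)
  id <- cumsum(new_grp)
  out <- segments(
    as.numeric(tapply(segs$start_s, id, min)),
    as.numeric(tapply(segs$end_s, id, max)),
    segs$activity[new_grp], segs$phase[new_grp]
  )
  label_track(out, foot = track$foot)
}

#' Enforce that bouts start and end with a swing phase
#'
#' Any stance segment leading or trailing a bout of a cyclic activity is
#' relabeled rest (i.e., removed from the track, since rest is background).
#' A single stance separating two different non-rest activities at a
#' transition is exempt. Idempotent; never increases the labeled duration.
#'
#' @param track A `LabelTrack`.
#' @return A `LabelTrack`.
#' @export
enforce_swing_boundaries <- function(track) {
  repeat {
    segs <- track$segments
    n <- nrow(segs)
    if (n == 0) return(track)
    b <- bouts_of(track)
    drop <- integer(0)
    for (i in seq_len(nrow(b))) {
      if (!b$activity[i] %in% cyclic_activities()) next
      first <- b$first[i]; last <- b$last[i]
      # transition separator: a stance at a bout edge that is contiguous
      # with a different non-rest cyclic activity on its outer side (the
      # single stance allowed between two adjacent bouts) is exempt
      sep_before <- function(j) {
        j > 1 && segs$start_s[j] <= segs$end_s[j - 1] + 1e-6 &&
          segs$activity[j - 1] != segs$activity[j] &&
          segs$activity[j - 1] %in% cyclic_activities()
      }
      sep_after <- function(j) {
        j < n && segs$start_s[j + 1] <= segs$end_s[j] + 1e-6 &&
          segs$activity[j + 1] != segs$activity[j] &&
          segs$activity[j + 1] %in% cyclic_activities()
      }
      if (segs$phase[first] == "stance" && !sep_before(first)) {
        drop <- c(drop, first)
      }
      if (last != first && segs$phase[last] == "stance" &&
          !sep_after(last)) {
        drop <- c(drop, last)
      }
    }
    if (length(drop) == 0) return(track)
    track <- label_track(segs[-unique(drop), , drop = FALSE],
                         foot = track$foot)
  }
}

#' Flag statistically outlying cycles
#'
#' Computes per-activity cycle times (swing start to next swing start within
#' a bout) and swing-duration fractions, and flags cycles deviating more than
#' `k` standard deviations from the activity mean on either statistic. Labels
#' are never modified; this highlights cycles for reinspection. With fewer
#' than `min_cycles` cycles for an activity no flags are produced (warning).
#' `k = 0` is the degenerate limit where every cycle is flagged.
#'
#' @param track A `LabelTrack`.
#' @param k Deviation threshold in standard deviations.
#' @param min_cycles Minimum cycles per activity for stable statistics.
#' @return data.frame of flagged swing segments with columns of the segment
#'   plus `reason`.
#' @export
flag_outliers <- function(track, k = 3, min_cycles = 5) {
  segs <- track$segments
  empty <- cbind(segments(numeric(0), numeric(0), character(0), character(0)),
                 data.frame(reason = character(0)))
  if (nrow(segs) == 0) return(empty)
  b <- bouts_of(track)
  rows <- NULL
  for (i in seq_len(nrow(b))) {
    if (!b$activity[i] %in% cyclic_activities()) next
    idx <- seq(b$first[i], b$last[i])
    sw <- idx[segs$phase[idx] == "swing"]
    if (length(sw) < 2) next
    cyc_time <- diff(segs$start_s[sw])
    sw_frac <- (segs$end_s[sw] - segs$start_s[sw])[-length(sw)] / cyc_time
    rows <- rbind(rows, data.frame(seg = sw[-length(sw)],
                                   activity = b$activity[i],
                                   cycle_time = cyc_time,
                                   swing_frac = sw_frac))
  }
  if (is.null(rows)) {
    warning("no cycles found; no outlier statistics")
    return(empty)
  }
  out <- NULL
  for (act in unique(rows$activity)) {
    r <- rows[rows$activity == act, ]
    if (nrow(r) < min_cycles) {
      warning("fewer than ", min_cycles, " cycles for ", act,
              "; skipping outlier flags")
      next
    }
    dev_ct <- abs(r$cycle_time - mean(r$cycle_time))
    dev_sf <- abs(r$swing_frac - mean(r$swing_frac))
    flag <- if (k == 0) rep(TRUE, nrow(r)) else {
      dev_ct > k * stats::sd(r$cycle_time) | dev_sf > k * stats::sd(r$swing_frac)
    }
    if (any(flag)) {
      fs <- segs[r$seg[flag], , drop = FALSE]
      fs$reason <- ifelse((dev_ct > if (k == 0) -1 else k * stats::sd(r$cycle_time))[flag],
                          "cycle_time", "swing_fraction")
      out <- rbind(out, fs)
    }
  }
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
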