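## Event-based comparison of predicted and reference tracks: one-to-one
## boundary matching within a 50 ms tolerance, and the four summary metrics
## (F1, miss rate, false discovery rate, labeling effort).

#' Match predicted to reference boundary times
#'
#' Maximum-cardinality one-to-one matching between two sorted lists of
#' boundary times under an absolute-time tolerance. On a line this is solved
#' optimally by a greedy two-pointer sweep. Unmatched predictions are false
#' positives; unmatched references are false negatives.
#'
#' @param pred,ref Numeric vectors of boundary times (seconds), or boundary
#'   data.frames from [track_to_boundaries()].
#' @param tolerance_s Matching tolerance (default 0.05, i.e., 50 ms).
#' @return List of class `MatchResult`: `true_positive`, `false_positive`,
#'   `false_negative`, `pairs` (two-column matrix), `tolerance_s`.
#' @export
match_boundaries <- function(pred, ref, tolerance_s = 0.05) {
  if (is.data.frame(pred)) pred <- pred$time_s
  if (is.data.frame(ref)) ref <- ref$time_s
  pred <- sort(as.numeric(pred))
  ref <- sort(as.numeric(ref))
  i <- 1L; j <- 1L
  pairs <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("pred_time_s", "ref_time_s")))
  while (i <= length(pred) && j <= length(ref)) {
    d <- pred[i] - ref[j]
    if (abs(d) <= tolerance_s) {
      pairs <- rbind(pairs, c(pred[i], ref[j]))
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  structure(list(true_positive = nrow(pairs),
                 false_positive = length(pred) - nrow(pairs),
                 false_negative = length(ref) - nrow(pairs),
                 pairs = pairs, tolerance_s = tolerance_s),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("<MatchResult> TP = %d, FP = %d, FN = %d (tol %g ms)\n",
              x$true_positive, x$false_positive, x$false_negative,
              1000 * x$tolerance_s))
  invisible(x)
}

#' Compute the annotation metrics from a match result
#'
#' Exact evaluation of the four metrics:
#' F1 = 2TP / (2TP + FP + FN), miss rate = FN / (TP + FN),
#' false discovery rate = FP / (TP + FP), and labeling effort =
#' (FP + FN) / (TP + FN) — the fraction of labels that must be added or
#' deleted during manual correction, relative to the reference label count.
#' Undefined ratios (0/0) are reported as `NaN`, never silently 0. Effort is
#' not clamped and may exceed 1.
#'
#' @param match A `MatchResult`, or a list with elements `true_positive`,
#'   `false_positive`, `false_negative`.
#' @return List of class `MetricsReport` with fields `f1`, `miss_rate`,
#'   `false_discovery_rate`, `effort`, and the raw counts.
#' @export
compute_metrics <- function(match) {
  tp <- match$true_positive; fp <- match$false_positive
  fn <- match$false_negative
  div <- function(num, den) if (den == 0) NaN else num / den
  structure(list(
    f1 = div(2 * tp, 2 * tp + fp + fn),
    miss_rate = div(fn, tp + fn),
    false_discovery_rate = div(fp, tp + fp),
    effort = div(fp + fn, tp + fn),
    true_positive = tp, false_positive = fp, false_negative = fn
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "<MetricsReport> F1 = %.3f, MR = %.3f, FDR = %.3f, effort = %.3f\n",
    x$f1, x$miss_rate, x$false_discovery_rate, x$effort))
  invisible(x)
}

#' Evaluate a predicted track against a reference track
#'
#' Extracts boundary events from both tracks, excludes boundaries inside
#' reference `unknown` spans from both sides, matches them one-to-one within
#' the tolerance and reports global and per-activity metrics. Each reference
#' boundary is attributed to the activity of its right-hand segment (the
#' left-hand one at track end); unmatched predicted boundaries are attributed
#' the same way from the predicted track.
#'
#' @param pred,ref `LabelTrack`s for the same foot and time base.
#' @param tolerance_s Matching tolerance in seconds.
#' @return A `MetricsReport` with an extra `per_activity` element (named list
#'   of `MetricsReport`s).
#' @export
evaluate_tracks <- function(pred, ref, tolerance_s = 0.05) {
  if (pred$foot != ref$foot) stop("foot mismatch between tracks")
  pb <- track_to_boundaries(pred)
  rb <- track_to_boundaries(ref)
  unk <- ref$segments[ref$segments$activity == "unknown", , drop = FALSE]
  in_unknown <- function(times) {
    if (nrow(unk) == 0 || length(times) == 0) return(rep(FALSE, length(times)))
    vapply(times, function(t) {
      any(t > unk$start_s - tolerance_s & t < unk$end_s + tolerance_s)
    }, logical(1))
  }
  rb <- rb[rb$right_activity != "unknown" | is.na(rb$right_activity), ,
           drop = FALSE]
  rb <- rb[rb$left_activity != "unknown" | is.na(rb$left_activity), ,
           drop = FALSE]
  pb <- pb[!in_unknown(pb$time_s), , drop = FALSE]
  m <- match_boundaries(pb$time_s, rb$time_s, tolerance_s)
  rep_all <- compute_metrics(m)

  boundary_activity <- function(b) {
    ifelse(is.na(b$right_activity), b$left_activity, b$right_activity)
  }
  r_act <- boundary_activity(rb)
  p_act <- boundary_activity(pb)
  r_matched <- rb$time_s %in% m$pairs[, "ref_time_s"]
  p_matched <- pb$time_s %in% m$pairs[, "pred_time_s"]
  per <- list()
  for (act in unique(c(r_act, p_act))) {
    tp <- sum(r_matched & r_act == act)
    fn <- sum(!r_matched & r_act == act)
    fp <- sum(!p_matched & p_act == act)
    per[[act]] <- compute_metrics(list(true_positive = tp,
                                       false_positive = fp,
                                       false_negative = fn))
  }
  rep_all$per_activity <- per
  rep_all
}

#' Aggregate metric reports across subjects
#'
#' Mean and standard deviation of each metric over a list of reports,
#' matching the "mean over all subjects" convention of batch summaries.
#'
#' @param reports List of `MetricsReport`s.
#' @return data.frame with one row per metric: mean and sd.
#' @export
aggregate_reports <- function(reports) {
  grab <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  mets <- c("f1", "miss_rate", "false_discovery_rate", "effort")
  data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(grab(m), na.rm = TRUE), numeric(1)),
    sd = vapply(mets, function(m) stats::sd(grab(m)), numeric(1)),
    row.names = NULL
  )
}
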