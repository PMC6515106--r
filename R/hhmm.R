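## Hierarchical HMM for joint activity/phase segmentation, realized as a
## flattened HMM with a block-structured transition mask: each activity is a
## block (simple activities: 3 internal states for initiation, steady state,
## termination) or a pair of phase blocks (cyclic activities: 4 internal
## states per swing/stance phase; cycling: one 4-state block). Within a block
## transitions are left-right; the final state of every block connects to the
## entry state of every block. Emissions are diagonal-covariance Gaussian
## mixtures. Training is semi-supervised: frame labels pin down the block,
## the internal alignment is learned (Viterbi / segmental k-means
## re-estimation, deterministic given the corpus).

LOG_ZERO <- -1e30

#' Build an untrained hierarchical HMM
#'
#' @param acts Character vector of activities the model should cover
#'   (typically including `"rest"`).
#' @param feature_dim Number of feature dimensions.
#' @param n_internal_cyclic Internal states per phase block (default 4).
#' @param n_internal_simple Internal states per simple activity (default 3).
#' @return Object of class `HhmmModel` with uniform transition
#'   probabilities over the structural mask and unset emissions.
#' @export
build_model <- function(acts, feature_dim, n_internal_cyclic = 4L,
                        n_internal_simple = 3L) {
  acts <- unique(as.character(acts))
  if (length(acts) == 0) stop("empty activity set")
  bad <- setdiff(acts, setdiff(activities(), "unknown"))
  if (length(bad) > 0) stop("unknown activities: ", paste(bad, collapse = ", "))
  rows <- list()
  block <- 0L
  for (a in acts) {
    if (a %in% simple_activities()) {
      block <- block + 1L
      rows[[length(rows) + 1]] <- data.frame(
        activity = a, phase = "none",
        internal_index = seq_len(n_internal_simple) - 1L, block = block)
    } else if (a == "cycle") {
      block <- block + 1L
      rows[[length(rows) + 1]] <- data.frame(
        activity = a, phase = "none",
        internal_index = seq_len(n_internal_cyclic) - 1L, block = block)
    } else {
      for (ph in c("swing", "stance")) {
        block <- block + 1L
        rows[[length(rows) + 1]] <- data.frame(
          activity = a, phase = ph,
          internal_index = seq_len(n_internal_cyclic) - 1L, block = block)
      }
    }
  }
  states <- do.call(rbind, rows)
  S <- nrow(states)
  first <- !duplicated(states$block)
  last <- !duplicated(states$block, fromLast = TRUE)
  mask <- matrix(FALSE, S, S)
  for (s in seq_len(S)) {
    mask[s, s] <- TRUE                          # self-loop (left-right)
    if (!last[s]) mask[s, s + 1L] <- TRUE       # forward within block
    if (last[s]) mask[s, first] <- TRUE         # block exit -> all entries
  }
  trans <- mask * 1
  trans <- trans / rowSums(trans)
  init <- ifelse(first, 1 / sum(first), 0)
  structure(list(states = states, mask = mask, trans = trans, init = init,
                 emissions = NULL, feature_dim = as.integer(feature_dim)),
            class = "HhmmModel")
}

#' @export
print.HhmmModel <- function(x, ...) {
  cat(sprintf("<HhmmModel> %d states, %d blocks, %d activities, D = %d%s\n",
              nrow(x$states), max(x$states$block),
              length(unique(x$states$activity)), x$feature_dim,
              if (is.null(x$emissions)) " (emissions unset)" else ""))
  invisible(x)
}

## internal helpers ----------------------------------------------------------

stack_emissions <- function(model) {
  em <- model$emissions
  if (is.null(em)) stop("emissions not initialized; call init_emissions()")
  means <- do.call(rbind, lapply(em, `[[`, "mu"))
  vars <- do.call(rbind, lapply(em, `[[`, "var"))
  logw <- log(unlist(lapply(em, `[[`, "w")))
  ncomp <- vapply(em, function(e) length(e$w), integer(1))
  offsets <- as.integer(c(0, cumsum(ncomp)))
  list(means = means, vars = vars, logw = logw, offsets = offsets)
}

trans_sparse <- function(model) {
  S <- nrow(model$states)
  preds <- vector("list", S)
  vals <- vector("list", S)
  for (s in seq_len(S)) {
    p <- which(model$mask[, s])
    preds[[s]] <- as.integer(p - 1L)
    v <- log(model$trans[p, s])
    v[!is.finite(v)] <- LOG_ZERO
    vals[[s]] <- v
  }
  list(preds = preds, vals = vals)
}

emission_logdens <- function(model, X) {
  st <- stack_emissions(model)
  gmm_logdens_cpp(as.matrix(X), st$means, st$vars, st$logw, st$offsets)
}

# frame-wise (activity, phase) labels implied by a track; uncovered time is
# background rest
frame_labels <- function(track, times) {
  act <- rep("rest", length(times))
  ph <- rep("none", length(times))
  segs <- track$segments
  if (nrow(segs) > 0 && length(times) > 0) {
    j <- findInterval(times, segs$start_s)
    inside <- j >= 1
    inside[inside] <- times[inside] < segs$end_s[j[inside]]
    act[inside] <- segs$activity[j[inside]]
    ph[inside] <- segs$phase[j[inside]]
  }
  data.frame(activity = act, phase = ph, stringsAsFactors = FALSE)
}

# block id per frame (NA when the label has no block in the model: frame is
# left unconstrained and counted as skipped)
frame_block_ids <- function(model, labels) {
  key <- paste(model$states$activity, model$states$phase)
  blk <- model$states$block[!duplicated(model$states$block)]
  bkey <- key[!duplicated(model$states$block)]
  match(paste(labels$activity, labels$phase), bkey)
}

mask_logobs_blocks <- function(logobs, state_blocks, fb) {
  allowed <- outer(state_blocks, fb, "==")
  allowed[, is.na(fb)] <- TRUE
  logobs[!allowed] <- LOG_ZERO
  logobs
}

fit_diag_gaussian <- function(X, floor = 1e-6) {
  mu <- colMeans(X)
  v <- pmax(colMeans(X^2) - mu^2, floor)
  list(w = 1, mu = matrix(mu, 1), var = matrix(v, 1))
}

# Small diagonal-covariance GMM fit: linear split init, fixed EM iterations.
fit_diag_gmm <- function(X, k, n_iter = 10, floor = 1e-6) {
  n <- nrow(X)
  if (k == 1 || n < 2 * k) return(fit_diag_gaussian(X, floor))
  part <- floor((seq_len(n) - 1) * k / n) + 1
  mu <- do.call(rbind, lapply(1:k, function(c) colMeans(X[part == c, , drop = FALSE])))
  v <- do.call(rbind, lapply(1:k, function(c) {
    pmax(apply(X[part == c, , drop = FALSE], 2, stats::var), floor)
  }))
  w <- rep(1 / k, k)
  for (it in seq_len(n_iter)) {
    ld <- vapply(1:k, function(c) {
      -0.5 * colSums((t(X) - mu[c, ])^2 / v[c, ]) -
        0.5 * sum(log(2 * pi * v[c, ])) + log(w[c])
    }, numeric(n))
    m <- apply(ld, 1, max)
    r <- exp(ld - m)
    r <- r / rowSums(r)
    nk <- colSums(r)
    w <- nk / n
    for (c in 1:k) {
      mu[c, ] <- colSums(r[, c] * X) / nk[c]
      v[c, ] <- pmax(colSums(r[, c] * sweep(X, 2, mu[c, ])^2) / nk[c], floor)
    }
  }
  list(w = w, mu = mu, var = v)
}

## emissions initialization --------------------------------------------------

#' Initialize emissions from a labeled corpus (linear state split)
#'
#' Every labeled segment occurrence (and every maximal background-rest run)
#' is split into equal consecutive parts, one per internal state of its
#' block, in order. Each state's Gaussian (mixture) is then fitted to its
#' assigned frames: `components` mixture components, diagonal covariance,
#' a fixed number of EM iterations (10), variances floored. States with no
#' frames are seeded from the global feature distribution with a warning.
#'
#' @param model An `HhmmModel`.
#' @param corpus List of items, each a list with elements `features`
#'   (`FeatureMatrix`) and `track` (`LabelTrack`).
#' @param components Mixture components per state (default 1).
#' @param em_iterations EM iterations for mixture fitting.
#' @param variance_floor Lower bound on variances.
#' @return The model with emissions set.
#' @export
init_emissions <- function(model, corpus, components = 1L,
                           em_iterations = 10L, variance_floor = 1e-3) {
  S <- nrow(model$states)
  pools <- vector("list", S)
  for (item in corpus) {
    X <- item$features$frames
    times <- item$features$frame_times_s
    lab <- frame_labels(item$track, times)
    fb <- frame_block_ids(model, lab)
    # occurrence = maximal run of frames in one block
    r <- rle(ifelse(is.na(fb), -1L, fb))
    pos <- 1L
    for (ri in seq_along(r$lengths)) {
      len <- r$lengths[ri]
      blk <- r$values[ri]
      if (blk > 0) {
        sts <- which(model$states$block == blk)  # ordered by internal index
        part <- floor((seq_len(len) - 1) * length(sts) / len) + 1
        for (p in unique(part)) {
          s <- sts[p]
          pools[[s]] <- rbind(pools[[s]],
                              X[pos + which(part == p) - 1L, , drop = FALSE])
        }
      }
      pos <- pos + len
    }
  }
  allX <- do.call(rbind, lapply(corpus, function(it) it$features$frames))
  global <- fit_diag_gaussian(allX, variance_floor)
  em <- vector("list", S)
  for (s in seq_len(S)) {
    if (is.null(pools[[s]]) || nrow(pools[[s]]) == 0) {
      warning("state ", s, " (", model$states$activity[s], "/",
              model$states$phase[s], ") has no frames; seeded globally")
      em[[s]] <- global
    } else {
      em[[s]] <- fit_diag_gmm(pools[[s]], components, em_iterations,
                              variance_floor)
    }
  }
  model$emissions <- em
  model
}

## training ------------------------------------------------------------------

#' Semi-supervised hHMM training
#'
#' Label-constrained Viterbi (segmental k-means) re-estimation: per
#' iteration, each frame's admissible states are restricted to the block
#' named by its label track (background time is rest); the best constrained
#' state path is found and transition probabilities, initial distribution and
#' Gaussian parameters are re-estimated from the alignment. Structural zeros
#' are preserved and rows stay stochastic. The per-iteration constrained
#' log-likelihood is recorded and is non-decreasing; training is a
#' deterministic fixed point, so iterations after the alignment stops
#' changing are no-ops (they are short-circuited and the history padded with
#' the fixed-point value).
#'
#' @param model An `HhmmModel` with initialized emissions.
#' @param corpus List of items with `features` and `track` (see
#'   [init_emissions()]).
#' @param n_iterations Training iterations (default 100).
#' @param variance_floor Lower bound on re-estimated variances.
#' @return The trained model, with attributes `log_likelihood_history`
#'   (one entry per iteration) and `n_frames_skipped`.
#' @export
train_hhmm <- function(model, corpus, n_iterations = 100,
                       variance_floor = 1e-3) {
  if (is.null(model$emissions)) stop("emissions not initialized")
  if (n_iterations == 0) {
    attr(model, "log_likelihood_history") <- numeric(0)
    return(model)
  }
  S <- nrow(model$states)
  D <- model$feature_dim
  sb <- model$states$block
  seqs <- lapply(corpus, function(item) {
    X <- as.matrix(item$features$frames)
    lab <- frame_labels(item$track, item$features$frame_times_s)
    fb <- frame_block_ids(model, lab)
    list(X = X, fb = fb)
  })
  n_frames <- sum(vapply(seqs, function(s) nrow(s$X), numeric(1)))
  skipped <- sum(vapply(seqs, function(s) sum(is.na(s$fb)), numeric(1)))
  history <- numeric(0)
  prev_paths <- NULL
  for (it in seq_len(n_iterations)) {
    sp <- trans_sparse(model)
    ll <- 0
    tc <- matrix(0, S, S)
    ic <- numeric(S)
    sum_x <- matrix(0, S, D)
    sum_x2 <- matrix(0, S, D)
    n_s <- numeric(S)
    paths <- vector("list", length(seqs))
    for (qi in seq_along(seqs)) {
      q <- seqs[[qi]]
      lo <- emission_logdens(model, q$X)
      lo <- mask_logobs_blocks(lo, sb, q$fb)
      vt <- viterbi_cpp(lo, log(pmax(model$init, 1e-300)), sp$preds, sp$vals)
      path <- vt$path + 1L
      paths[[qi]] <- path
      ll <- ll + vt$logp
      ic[path[1]] <- ic[path[1]] + 1
      if (length(path) > 1) {
        tc <- tc + matrix(tabulate(path[-length(path)] + S * (path[-1] - 1L),
                                   nbins = S * S), S, S)
      }
      rs <- rowsum(q$X, group = path)
      rs2 <- rowsum(q$X^2, group = path)
      ids <- as.integer(rownames(rs))
      sum_x[ids, ] <- sum_x[ids, ] + rs
      sum_x2[ids, ] <- sum_x2[ids, ] + rs2
      n_s <- n_s + tabulate(path, nbins = S)
    }
    history <- c(history, ll)
    converged <- !is.null(prev_paths) && identical(paths, prev_paths)
    if (converged) {
      history <- c(history, rep(ll, n_iterations - it))
      break
    }
    # M-step
    tc[!model$mask] <- 0
    rsums <- rowSums(tc)
    newt <- model$trans
    upd <- rsums > 0
    newt[upd, ] <- tc[upd, , drop = FALSE] / rsums[upd]
    newt[!model$mask] <- 0
    model$trans <- newt
    if (sum(ic) > 0) {
      entry <- !duplicated(model$states$block)
      ini <- ic / sum(ic)
      # keep a tiny mass on unused entry states so prediction can start
      ini[entry] <- ini[entry] + 1e-6
      ini <- ini / sum(ini)
      ini[!entry & ini == 0] <- 0
      model$init <- ini
    }
    for (s in which(n_s > 0)) {
      mu <- sum_x[s, ] / n_s[s]
      v <- pmax(sum_x2[s, ] / n_s[s] - mu^2, variance_floor)
      model$emissions[[s]] <- list(w = 1, mu = matrix(mu, 1),
                                   var = matrix(v, 1))
    }
    prev_paths <- paths
  }
  attr(model, "log_likelihood_history") <- history
  attr(model, "n_frames") <- n_frames
  attr(model, "n_frames_skipped") <- skipped
  model
}

## prediction ----------------------------------------------------------------

#' Task-restricted Viterbi prediction
#'
#' Decodes the best state path with, inside each task window, states of
#' activities not allowed in that window scored as impossible (rest is always
#' admissible; frames not covered by any window allow all activities). The
#' path is collapsed to segments of equal (activity, phase); rest spans are
#' background and omitted. Post-processing (merge + swing-boundary rule) is
#' applied by default.
#'
#' @param model A trained `HhmmModel`.
#' @param features A `FeatureMatrix` for one foot.
#' @param tasks Optional task-window data.frame.
#' @param foot Foot label for the output track.
#' @param postprocess Apply the label rules to the decoded track.
#' @return A `LabelTrack`.
#' @export
hhmm_predict <- function(model, features, tasks = NULL, foot = "left",
                         postprocess = TRUE) {
  X <- as.matrix(features$frames)
  if (ncol(X) != model$feature_dim) stop("feature_dim mismatch")
  times <- features$frame_times_s
  lo <- emission_logdens(model, X)
  if (!is.null(tasks) && nrow(tasks) > 0) {
    acts <- model$states$activity
    for (i in seq_len(nrow(tasks))) {
      sel <- times >= tasks$start_s[i] & times < tasks$end_s[i]
      if (!any(sel)) next
      allowed <- c(tasks$allowed_activities[[i]], "rest")
      lo[!(acts %in% allowed), sel] <- LOG_ZERO
    }
  }
  sp <- trans_sparse(model)
  vt <- viterbi_cpp(lo, log(pmax(model$init, 1e-300)), sp$preds, sp$vals)
  path <- vt$path + 1L
  act <- model$states$activity[path]
  ph <- model$states$phase[path]
  r <- rle(paste(act, ph, sep = "|"))
  ends <- cumsum(r$lengths)
  starts_i <- c(1L, head(ends, -1) + 1L)
  step <- features$step_s
  # segment bounds midway between neighboring frame centers
  bound <- c(times[1] - step / 2,
             (times[-length(times)] + times[-1]) / 2,
             times[length(times)] + step / 2)
  seg_start <- bound[starts_i]
  seg_end <- bound[ends + 1L]
  lab <- do.call(rbind, strsplit(r$values, "|", fixed = TRUE))
  keep <- lab[, 1] != "rest"
  tr <- label_track(segments(seg_start[keep], seg_end[keep],
                             lab[keep, 1], lab[keep, 2]), foot = foot)
  if (postprocess) tr <- enforce_swing_boundaries(merge_consecutive(tr))
  attr(tr, "log_likelihood") <- vt$logp
  tr
}

## simulation and persistence ------------------------------------------------

#' Simulate observations from an hHMM
#'
#' Samples a state path from the initial/transition distributions and
#' Gaussian observations from the state emissions. Used for parameter
#' recovery checks. Also returns the implied label track (frame spacing
#' `step_s`).
#'
#' @param model A trained or initialized `HhmmModel`.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param step_s Nominal frame spacing for the label track.
#' @return List with `X`, `states` (1-based indices), `track`, `features`.
#' @export
simulate_hhmm <- function(model, n_frames, seed = 1, step_s = 0.005) {
  set.seed(seed)
  S <- nrow(model$states)
  st <- integer(n_frames)
  st[1] <- sample.int(S, 1, prob = model$init)
  for (t in seq_len(n_frames)[-1]) {
    st[t] <- sample.int(S, 1, prob = model$trans[st[t - 1], ])
  }
  D <- model$feature_dim
  X <- matrix(0, n_frames, D)
  for (t in seq_len(n_frames)) {
    e <- model$emissions[[st[t]]]
    c <- if (length(e$w) > 1) sample.int(length(e$w), 1, prob = e$w) else 1L
    X[t, ] <- stats::rnorm(D, e$mu[c, ], sqrt(e$var[c, ]))
  }
  act <- model$states$activity[st]
  ph <- model$states$phase[st]
  r <- rle(paste(act, ph, sep = "|"))
  ends <- cumsum(r$lengths)
  starts_i <- c(1L, head(ends, -1) + 1L)
  times <- (seq_len(n_frames) - 1) * step_s
  lab <- do.call(rbind, strsplit(r$values, "|", fixed = TRUE))
  keep <- lab[, 1] != "rest"
  tr <- label_track(segments(times[starts_i][keep],
                             times[ends][keep] + step_s,
                             lab[keep, 1], lab[keep, 2]), foot = "left")
  fm <- structure(list(frames = X, frame_times_s = times + step_s / 2,
                       window_s = step_s, step_s = step_s),
                  class = "FeatureMatrix")
  list(X = X, states = st, track = tr, features = fm)
}

#' Save / load an hHMM model as JSON
#'
#' @param model An `HhmmModel`.
#' @param path File path (`.json`).
#' @return `load_model()` returns an `HhmmModel`.
#' @export
save_model <- function(model, path) {
  em <- NULL
  if (!is.null(model$emissions)) {
    em <- lapply(model$emissions, function(e) {
      list(w = as.numeric(e$w), ncomp = length(e$w),
           mu = as.numeric(t(e$mu)), var = as.numeric(t(e$var)))
    })
  }
  obj <- list(states = as.list(model$states), mask = as.vector(model$mask),
              trans = as.vector(model$trans), init = model$init,
              feature_dim = model$feature_dim, emissions = em,
              log_likelihood_history = attr(model, "log_likelihood_history"))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  D <- as.integer(obj$feature_dim)
  states <- data.frame(activity = obj$states$activity,
                       phase = obj$states$phase,
                       internal_index = obj$states$internal_index,
                       block = obj$states$block, stringsAsFactors = FALSE)
  S <- nrow(states)
  em <- NULL
  if (!is.null(obj$emissions)) {
    em <- lapply(obj$emissions, function(e) {
      list(w = as.numeric(e$w),
           mu = matrix(as.numeric(e$mu), nrow = e$ncomp, byrow = TRUE),
           var = matrix(as.numeric(e$var), nrow = e$ncomp, byrow = TRUE))
    })
  }
  m <- structure(list(states = states, mask = matrix(as.logical(obj$mask), S),
                      trans = matrix(as.numeric(obj$trans), S),
                      init = as.numeric(obj$init), emissions = em,
                      feature_dim = D),
                 class = "HhmmModel")
  attr(m, "log_likelihood_history") <- obj$log_likelihood_history
  m
}

## iterative batch protocol --------------------------------------------------

#' Iterative batch training protocol
#'
#' Mirrors the annotation workflow: train on batch 1, predict batch 2, score
#' it against its reference, add batch 2's (corrected) labels to the training
#' set, retrain warm-started from the previous model, and so on. Optionally
#' scores every intermediate model on a fixed holdout batch.
#'
#' @param batches List (length >= 2) of corpora; each corpus is a list of
#'   items with `features`, `track` and optionally `tasks`.
#' @param acts Activities for the model (default: all present plus rest).
#' @param n_iterations Training iterations per stage.
#' @param holdout Optional corpus scored with every model.
#' @param components,variance_floor Emission settings.
#' @return List with `models` (per batch), `batch_reports` (per batch >= 2:
#'   list of `MetricsReport` per item) and `holdout_reports`.
#' @export
iterative_protocol <- function(batches, acts = NULL, n_iterations = 100,
                               holdout = NULL, components = 1L,
                               variance_floor = 1e-3) {
  if (length(batches) < 2) stop("need at least 2 batches")
  if (any(vapply(batches, length, integer(1)) == 0)) stop("empty batch")
  if (is.null(acts)) {
    acts <- unique(unlist(lapply(batches, function(b) {
      unlist(lapply(b, function(it) unique(it$track$segments$activity)))
    })))
    acts <- unique(c(acts, "rest"))
  }
  D <- ncol(batches[[1]][[1]]$features$frames)
  model <- build_model(acts, D)
  model <- init_emissions(model, batches[[1]], components = components,
                          variance_floor = variance_floor)
  model <- train_hhmm(model, batches[[1]], n_iterations, variance_floor)
  models <- list(model)
  batch_reports <- vector("list", length(batches))
  score_corpus <- function(model, corpus) {
    lapply(corpus, function(it) {
      pred <- hhmm_predict(model, it$features, it$tasks,
                           foot = it$track$foot)
      evaluate_tracks(pred, it$track)
    })
  }
  for (k in 2:length(batches)) {
    batch_reports[[k]] <- score_corpus(models[[k - 1]], batches[[k]])
    model <- train_hhmm(models[[k - 1]], do.call(c, batches[seq_len(k)]),
                        n_iterations, variance_floor)
    models[[k]] <- model
  }
  holdout_reports <- NULL
  if (!is.null(holdout)) {
    holdout_reports <- lapply(models, score_corpus, corpus = holdout)
  }
  list(models = models, batch_reports = batch_reports,
       holdout_reports = holdout_reports)
}
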