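# Independent brute-force oracles and random-case generators used across the
# suite. These deliberately re-derive results from definitions (exhaustive
# search / naive loops) rather than reusing package internals.

# Maximum-cardinality one-to-one matching between two event lists under an
# absolute tolerance, by exhaustive recursion with pruning.
oracle_max_matching <- function(pred, ref, tol) {
  n <- length(ref)
  best <- 0L
  used <- rep(FALSE, length(pred))
  rec <- function(j, count) {
    if (count + (n - j + 1L) <= best) return()
    if (j > n) {
      best <<- max(best, count)
      return()
    }
    for (i in seq_along(pred)) {
      if (!used[i] && abs(pred[i] - ref[j]) <= tol) {
        used[i] <<- TRUE
        rec(j + 1L, count + 1L)
        used[i] <<- FALSE
      }
    }
    rec(j + 1L, count)  # leave ref j unmatched
  }
  rec(1L, 0L)
  best
}

# Exhaustive best-path search over the allowed-transition graph.
oracle_viterbi <- function(logobs, loginit, mask, logtrans) {
  S <- nrow(logobs)
  Tn <- ncol(logobs)
  paths <- matrix(seq_len(S), ncol = 1)
  scores <- loginit + logobs[, 1]
  for (t in seq_len(Tn)[-1]) {
    np <- list()
    ns <- numeric(0)
    for (k in seq_len(nrow(paths))) {
      s <- paths[k, t - 1]
      for (s2 in which(mask[s, ])) {
        np[[length(np) + 1]] <- c(paths[k, ], s2)
        ns <- c(ns, scores[k] + logtrans[s, s2] + logobs[s2, t])
      }
    }
    paths <- do.call(rbind, np)
    scores <- ns
  }
  k <- which.max(scores)
  list(path = paths[k, ], logp = scores[k])
}

# Naive peak picking from the definition: all local maxima, height filter,
# greedy-by-height pruning with pairwise distance checks (earlier wins ties).
oracle_pd <- function(x, rate, min_dist_s, min_h) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] >= min_h) {
      cand <- c(cand, i)
    }
  }
  ord <- cand[order(-x[cand], cand)]
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in acc) if (abs(i - j) < min_dist_s * rate) ok <- FALSE
    if (ok) acc <- c(acc, i)
  }
  sort(acc)
}

# Random small hHMM with valid structure and well-behaved parameters.
random_small_model <- function(seed, feature_dim = 2) {
  set.seed(seed)
  acts <- list(c("rest", "sit"), c("rest", "cycle"), c("rest", "walk"),
               c("rest", "sit", "cycle"))[[sample(4, 1)]]
  m <- build_model(acts, feature_dim)
  S <- nrow(m$states)
  tr <- matrix(0, S, S)
  for (s in seq_len(S)) {
    p <- stats::runif(sum(m$mask[s, ]), 0.1, 1)
    tr[s, m$mask[s, ]] <- p / sum(p)
  }
  m$trans <- tr
  entry <- !duplicated(m$states$block)
  ini <- rep(0, S)
  ini[entry] <- stats::runif(sum(entry), 0.1, 1)
  m$init <- ini / sum(ini)
  m$emissions <- lapply(seq_len(S), function(s) {
    list(w = 1, mu = matrix(stats::rnorm(feature_dim, s, 0.5), 1),
         var = matrix(stats::runif(feature_dim, 0.2, 1), 1))
  })
  m
}

# Random structurally valid track whose bouts alternate phases but may lead
# or trail with a stance, and whose segments may be split into contiguous
# equal-label pieces (the raw-prediction flaws post-processing must fix).
random_perturbed_track <- function(seed) {
  set.seed(seed)
  acts <- sample(cyclic_activities(), sample(1:3, 1))
  t <- stats::runif(1, 0, 1)
  segs <- NULL
  for (a in acts) {
    t <- t + stats::runif(1, 0.5, 2)
    phases <- rep(c("swing", "stance"), sample(3:6, 1))
    if (stats::runif(1) < 0.4) phases <- c("stance", phases)  # bad lead
    if (stats::runif(1) < 0.4) phases <- c(phases, "stance")  # bad trail
    if (phases[length(phases)] == "swing" && stats::runif(1) < 0.5) {
      phases <- head(phases, -1)  # end on stance sometimes
    }
    for (ph in phases) {
      dur <- stats::runif(1, 0.2, 0.6)
      # occasionally split one segment into 2-3 contiguous pieces
      k <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
      cuts <- sort(stats::runif(k - 1, 0.2, 0.8)) * dur
      bounds <- c(0, cuts, dur)
      segs <- rbind(segs, segments(t + head(bounds, -1), t + bounds[-1],
                                   a, ph))
      t <- t + dur
    }
  }
  label_track(segs, foot = "left")
}

# Tiny feature corpus: one item with given per-frame values and a track
# labeling them.
tiny_corpus_item <- function(values, track, step_s = 0.01) {
  X <- matrix(values, ncol = 1)
  fm <- structure(list(frames = X,
                       frame_times_s = (seq_along(values) - 0.5) * step_s,
                       window_s = step_s, step_s = step_s),
                  class = "FeatureMatrix")
  list(features = fm, track = track)
}
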