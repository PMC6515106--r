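test_that("model architecture produces the prescribed state counts", {
  m <- build_model(c("rest", "walk"), 10)
  expect_equal(nrow(m$states), 11)  # 3 + 2 x 4
  m2 <- build_model("rest", 4)
  expect_equal(nrow(m2$states), 3)
  # pure left-right with self-loops; block exit may re-enter
  want_mask <- matrix(FALSE, 3, 3)
  want_mask[1, 1] <- want_mask[1, 2] <- TRUE
  want_mask[2, 2] <- want_mask[2, 3] <- TRUE
  want_mask[3, 3] <- want_mask[3, 1] <- TRUE
  expect_equal(m2$mask, want_mask)
  # full 12-activity set vs independent counting of the architecture rules
  acts <- setdiff(activities(), "unknown")
  m3 <- build_model(acts, 10)
  want <- 3 * length(intersect(acts, simple_activities())) +
    8 * length(intersect(acts, cyclic_activities())) +
    4 * ("cycle" %in% acts)
  expect_equal(nrow(m3$states), want)
  expect_error(build_model(character(0), 2), "empty")
  # rows are stochastic and structural zeros hold from the start
  expect_equal(rowSums(m3$trans), rep(1, nrow(m3$states)))
  expect_true(all(m3$trans[!m3$mask] == 0))
})

test_that("linear initialization splits segments across internal states", {
  # 8 frames in one stance block of 4 states: pairs {1,2},{3,4},{5,6},{7,8}
  track <- label_track(segments(0, 0.08, "walk", "stance"))
  item <- tiny_corpus_item(c(10, 10, 20, 20, 30, 30, 40, 40), track)
  m <- build_model(c("rest", "walk"), 1)
  m <- suppressWarnings(init_emissions(m, list(item)))
  stance <- which(m$states$activity == "walk" & m$states$phase == "stance")
  mus <- vapply(stance, function(s) m$emissions[[s]]$mu[1, 1], numeric(1))
  expect_equal(mus, c(10, 20, 30, 40))
  # identical frames: variance floor engages, no failure
  item2 <- tiny_corpus_item(rep(5, 8), track)
  m2 <- suppressWarnings(init_emissions(m, list(item2)))
  expect_true(all(vapply(stance, function(s) m2$emissions[[s]]$var[1, 1],
                         numeric(1)) >= 1e-6))
  # unpopulated states are seeded globally with a warning
  suppressWarnings(
    expect_warning(init_emissions(build_model(c("rest", "walk"), 1),
                                  list(item)), "no frames"))
})

test_that("emission init recovers well-separated cluster centers", {
  set.seed(13)
  # one activity, frames drawn around per-state centers in order
  centers <- c(-6, -2, 2, 6)
  vals <- unlist(lapply(centers, function(c) rnorm(200, c, 0.3)))
  track <- label_track(segments(0, length(vals) * 0.01, "walk", "stance"))
  item <- tiny_corpus_item(vals, track)
  m <- build_model(c("rest", "walk"), 1)
  m <- suppressWarnings(init_emissions(m, list(item)))
  stance <- which(m$states$activity == "walk" & m$states$phase == "stance")
  mus <- vapply(stance, function(s) m$emissions[[s]]$mu[1, 1], numeric(1))
  expect_true(all(abs(mus - centers) < 0.1 * 0.3))  # within 0.1 cluster sd
})

test_that("masked Viterbi equals exhaustive path enumeration", {
  for (seed in 1:50) {
    m <- random_small_model(seed)
    set.seed(seed + 1000)
    S <- nrow(m$states)
    Tn <- sample(4:8, 1)
    lo <- matrix(rnorm(S * Tn), S, Tn)
    # random task-style masking of one activity on a few frames
    if (runif(1) < 0.5) {
      act <- sample(unique(m$states$activity), 1)
      frames <- sample(Tn, min(2, Tn))
      lo[m$states$activity == act, frames] <- -1e30
    }
    sp <- cyclephase:::trans_sparse(m)
    got <- viterbi_cpp(lo, log(pmax(m$init, 1e-300)), sp$preds, sp$vals)
    logtrans <- log(m$trans)
    logtrans[!m$mask] <- -Inf
    want <- oracle_viterbi(lo, log(pmax(m$init, 1e-300)), m$mask, logtrans)
    expect_equal(got$logp, want$logp, tolerance = 1e-9)
    expect_equal(got$path + 1L, want$path)
  }
})

test_that("training likelihood is monotone and respects structure", {
  sub <- generate_subject(subject_scenario(seed = 61))
  cfg <- default_config()
  corpus <- cyclephase:::subject_to_corpus_items(sub, cfg)[1]
  m <- build_model(c("rest", "walk", "jog", "run"), 10)
  m <- init_emissions(m, corpus)
  m0 <- m
  mt <- train_hhmm(m, corpus, 30)
  h <- attr(mt, "log_likelihood_history")
  expect_length(h, 30)
  expect_true(all(diff(h) >= -1e-6 * attr(mt, "n_frames")))
  expect_true(all(mt$trans[!mt$mask] == 0))
  expect_equal(rowSums(mt$trans), rep(1, nrow(mt$states)), tolerance = 1e-9)
  # zero iterations: unchanged model
  m_id <- train_hhmm(m0, corpus, 0)
  expect_equal(m_id$trans, m0$trans)
  expect_equal(m_id$emissions, m0$emissions)
  # training is a deterministic fixed point: 2 x 15 iterations from the same
  # init equals 30 straight iterations
  m_a <- train_hhmm(train_hhmm(m0, corpus, 15), corpus, 15)
  expect_equal(tail(attr(m_a, "log_likelihood_history"), 1), tail(h, 1),
               tolerance = 1e-8)
})

test_that("prediction respects task restrictions and collapses runs", {
  sub <- generate_subject(subject_scenario(seed = 63))
  cfg <- default_config()
  items <- cyclephase:::subject_to_corpus_items(sub, cfg)
  m <- build_model(c("rest", "walk", "jog", "run"), 10)
  m <- init_emissions(m, items)
  m <- train_hhmm(m, items, 20)
  # single-activity window over the whole recording: only that activity
  whole <- task_windows(0, 1e6, "walk_only", list("walk"))
  tr <- hhmm_predict(m, items[[1]]$features, whole)
  expect_true(all(tr$segments$activity == "walk"))
  expect_invisible(check_track_invariants(tr))
  expect_error(hhmm_predict(m, structure(list(frames = matrix(0, 5, 3),
                                              frame_times_s = 1:5 / 10,
                                              step_s = 0.1),
                                         class = "FeatureMatrix")),
               "feature_dim")
})

test_that("parameters are recovered from data simulated by the model", {
  truth <- random_small_model(99)  # rest + walk, 11 states
  truth <- local({
    m <- build_model(c("rest", "walk"), 2)
    S <- nrow(m$states)
    tr <- matrix(0, S, S)
    entry <- which(!duplicated(m$states$block))
    last <- which(!duplicated(m$states$block, fromLast = TRUE))
    for (s in seq_len(S)) {
      if (s %in% last) {
        tr[s, s] <- 0.5
        tr[s, entry] <- tr[s, entry] + 0.5 / length(entry)
      } else {
        tr[s, s] <- 0.7
        tr[s, s + 1] <- 0.3
      }
    }
    m$trans <- tr
    m$init <- ifelse(seq_len(S) == 1, 1, 0)
    m$emissions <- lapply(seq_len(S), function(s) {
      list(w = 1, mu = matrix(c(2 * s, -s %% 3), 1),
           var = matrix(c(0.09, 0.09), 1))
    })
    m
  })
  sim <- simulate_hhmm(truth, 5000, seed = 14)
  fit <- build_model(c("rest", "walk"), 2)
  fit <- suppressWarnings(init_emissions(
    fit, list(list(features = sim$features, track = sim$track))))
  fit <- train_hhmm(fit, list(list(features = sim$features,
                                   track = sim$track)), 50)
  visited <- tabulate(sim$states, nbins = nrow(truth$states)) > 50
  expect_true(all(abs(fit$trans[visited, ] - truth$trans[visited, ]) < 0.05))
})

test_that("models persist through JSON round trips", {
  m <- random_small_model(3)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  back <- load_model(f)
  expect_equal(back$trans, m$trans, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$states$activity, m$states$activity)
  for (s in seq_len(nrow(m$states))) {
    expect_equal(back$emissions[[s]]$mu, m$emissions[[s]]$mu,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("iterative protocol improves or maintains holdout effort", {
  expect_error(iterative_protocol(list(list())), "at least 2")
  cfg <- default_config()
  subs <- generate_batch(4, 71)
  items <- lapply(subs, function(s) {
    cyclephase:::subject_to_corpus_items(s, cfg)[[1]]  # left foot only
  })
  res <- iterative_protocol(list(items[1], items[2], items[3]),
                            n_iterations = 20, holdout = items[4])
  expect_length(res$models, 3)
  eff <- vapply(res$holdout_reports,
                function(r) mean(vapply(r, `[[`, numeric(1), "effort")),
                numeric(1))
  expect_lte(eff[3], eff[1] + 0.05)
  # identical batches: batch-2 and batch-3 efforts agree within noise
  res2 <- iterative_protocol(list(items[1], items[1], items[1]),
                             n_iterations = 20)
  e2 <- mean(vapply(res2$batch_reports[[2]], `[[`, numeric(1), "effort"))
  e3 <- mean(vapply(res2$batch_reports[[3]], `[[`, numeric(1), "effort"))
  expect_lte(abs(e2 - e3), 0.05)
})
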