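test_that("training-set extraction aligns positives and isolates negatives", {
  cfg <- feature_config()
  set.seed(121)
  sim <- simulate_motion(event_frames = c(100L, 300L, 500L, 700L, 900L,
                                          1100L, 1300L, 1500L, 1700L, 1900L),
                         n_frames = 2100L, cfg = sim_config(seed = 5L))
  ts <- make_training_set(sim$seq, sim$event_frames, cfg, neg_ratio = 3,
                          seed = 5L)
  expect_equal(sum(ts$labels == "1"), 10L)             # one window per action
  expect_equal(sum(ts$labels == "0"), 30L)
  expect_equal(ncol(ts$features), 300L)

  # an event too close to the end is skipped with a warning
  expect_warning(
    ts2 <- make_training_set(sim$seq, c(100L, 2090L), cfg, seed = 5L),
    "skipped")
  expect_equal(sum(ts2$labels == "1"), 1L)

  expect_error(make_training_set(sim$seq, integer(0), cfg), "no annotated")
})

test_that("negative windows never overlap a true action interval", {
  cfg <- feature_config()
  set.seed(131)
  sim <- simulate_motion(event_frames = seq(200L, 3000L, by = 200L),
                         n_frames = 3200L, cfg = sim_config(seed = 6L))
  x <- sim$seq$data
  events <- sim$event_frames
  ts <- make_training_set(sim$seq, events, cfg, neg_ratio = Inf, seed = 6L)
  # recover negative start frames by re-deriving the rule and comparing
  # against an exhaustive interval-overlap check
  all_starts <- 0:(nrow(x) - cfg$l_w)
  neg <- all_starts[vapply(all_starts,
                           function(s) all(abs(s - events) > cfg$l_w), TRUE)]
  for (s in neg) {
    overlaps <- any(pmax(s, events) < pmin(s + cfg$l_w, events + cfg$l_w))
    expect_false(overlaps)
  }
  expect_equal(sum(ts$labels == "0"), length(neg))
})

test_that("the classifier separates classes, is seed-deterministic, and generalizes", {
  cfg <- feature_config()
  scfg <- sim_config(seed = 8L)
  ev_a <- seq(200L, 15000L, by = 150L)
  sim_a <- simulate_motion(ev_a, 15500L, scfg)
  ts <- make_training_set(smooth_motion(sim_a$seq), sim_a$event_frames, cfg,
                          seed = 8L)
  model <- train_classifier(ts$features, ts$labels, seed = 8L)

  # separability on seen data
  post <- predict(model, ts$features)
  expect_gt(mean(post[ts$labels == "1"]), mean(post[ts$labels == "0"]))

  # retraining under the same seed reproduces the predictions exactly
  model2 <- train_classifier(ts$features, ts$labels, seed = 8L)
  expect_identical(predict(model2, ts$features), post)

  expect_error(train_classifier(ts$features, factor(rep("1", nrow(ts$features)),
                                                    levels = c("0", "1"))),
               "both classes")

  # held-out day with a different seed: window-level AUC above 0.95
  scfg_b <- sim_config(seed = 88L)
  ev_b <- seq(300L, 14000L, by = 170L)
  sim_b <- simulate_motion(ev_b, 14500L, scfg_b)
  ts_b <- make_training_set(smooth_motion(sim_b$seq), sim_b$event_frames, cfg,
                            seed = 88L)
  post_b <- predict(model, ts_b$features)
  lab_b <- ts_b$labels == "1"
  r <- rank(post_b)
  auc <- (sum(r[lab_b]) - sum(lab_b) * (sum(lab_b) + 1) / 2) /
    (sum(lab_b) * sum(!lab_b))
  expect_gt(auc, 0.95)
})

test_that("event extraction follows the local-maximum and spacing rules", {
  # single smooth peak above threshold
  a <- c(0.1, 0.3, 0.9, 0.4, 0.1)
  ev <- detect_events(a, th_a = 0.5, l_w = 1L)
  expect_equal(ev$events$frame, 2L)
  expect_equal(ev$events$posterior, 0.9)

  # two peaks 60 frames apart with l_w = 50: the second is suppressed
  a2 <- rep(0, 200)
  a2[c(51, 111)] <- c(0.9, 0.95)
  ev2 <- detect_events(a2, 0.5, 50L)
  expect_equal(ev2$events$frame, 50L)

  # at exactly 2*l_w apart both survive
  a3 <- rep(0, 300)
  a3[c(51, 151)] <- 0.9
  expect_equal(detect_events(a3, 0.5, 50L)$events$frame, c(50L, 150L))

  # plateau: the first frame is the representative
  a4 <- c(0, 0.8, 0.8, 0.8, 0)
  expect_equal(detect_events(a4, 0.5, 1L)$events$frame, 1L)

  expect_equal(nrow(detect_events(rep(0.2, 50), 0.5, 50L)$events), 0L)
  expect_error(detect_events(a, th_a = 0), "0, 1")
})

test_that("event extraction matches brute-force rule application on random posteriors", {
  set.seed(141)
  for (rep in 1:50) {
    a <- round(runif(200), 2)
    lw <- sample(c(3L, 10L, 25L), 1)
    th <- runif(1, 0.3, 0.7)
    got <- detect_events(a, th, lw)$events$frame
    expect_equal(got, oracle_detect(a, th, lw))
    # accepted events always >= 2*l_w apart
    if (length(got) > 1) expect_true(all(diff(got) >= 2 * lw))
  }
})

test_that("delaying the sequence delays every detected event by exactly k", {
  cfg <- feature_config()
  scfg <- sim_config(seed = 12L)
  ev <- seq(400L, 9000L, by = 400L)
  sim <- simulate_motion(ev, 9500L, scfg)
  sm <- smooth_motion(sim$seq)
  ts <- make_training_set(sm, sim$event_frames, cfg, seed = 12L)
  model <- train_classifier(ts$features, ts$labels, seed = 12L)

  post <- score_sequence(model, sm, cfg)
  base <- detect_events(post, 0.5, cfg$l_w)$events$frame
  expect_gt(length(base), 10)

  k <- 137L
  delayed <- rbind(matrix(0, k, ncol(sm$data)), sm$data)
  post_d <- score_sequence(model, motion_sequence(delayed, 50), cfg)
  shifted <- detect_events(post_d, 0.5, cfg$l_w)$events$frame
  expect_equal(shifted, base + k)
})

test_that("score_sequence covers every window start and stays in [0, 1]", {
  cfg <- feature_config()
  scfg <- sim_config(seed = 13L)
  sim <- simulate_motion(c(200L, 500L), 800L, scfg)
  sm <- smooth_motion(sim$seq)
  ts <- make_training_set(sm, sim$event_frames, cfg, neg_ratio = Inf, seed = 13L)
  model <- train_classifier(ts$features, ts$labels, seed = 13L)
  post <- score_sequence(model, sm, cfg)
  expect_length(post, 800 - cfg$l_w + 1)
  expect_true(all(post >= 0 & post <= 1))
  expect_error(score_sequence(model, motion_sequence(sm$data[1:10, ], 50), cfg),
               "shorter")
})
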