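test_that("responses slice exactly one event window each", {
  cfg <- msg_config(60, event_duration_s = 2, rng_seed = 8)
  log <- simulate_msg(cfg, player_model(seed = 9))
  rs <- segment_responses(log)
  expect_length(rs, 30)
  expect_true(all(vapply(rs, function(r) length(r$paddle), integer(1)) == 200L))
  expect_true(all(vapply(rs, function(r) r$t_ms[1], numeric(1)) == 0))

  # zero-event log -> empty list
  empty <- session_log(msg_config(duration_s = 0, rng_seed = 1),
                       sample_schema()[0, ])
  expect_length(segment_responses(empty), 0)

  # hand-built 2-event log: slices equal manual index arithmetic
  cfg2 <- msg_config(4, event_duration_s = 2, rng_seed = 3)
  log2 <- make_msg_log(cfg2, function(t, ev) seq(0, 1, length.out = length(t)))
  rs2 <- segment_responses(log2)
  expect_equal(rs2[[1]]$paddle, log2$samples$paddle_pos[1:200])
  expect_equal(rs2[[2]]$paddle, log2$samples$paddle_pos[201:400])
  expect_equal(rs2[[2]]$t_ms, log2$samples$t_ms[201:400] - 2000)

  # an event window with missing samples names the event
  broken <- log2
  broken$events$t_disappear_ms[2] <- 4500
  broken$events$t_appear_ms[2] <- 2500
  expect_error(segment_responses(broken), "event 2")
})

test_that("movement onset honours the no-movement and step contracts", {
  cfg <- msg_config(4, event_duration_s = 2, rng_seed = 13)
  # motionless paddle -> NA
  log <- make_msg_log(cfg, function(t, ev) rep(0.2, length(t)))
  rs <- segment_responses(log)
  expect_true(is.na(movement_onset(rs[[1]], cfg)))
  # paddle at the arrival position from the first sample -> onset at time zero
  ev1_end <- schedule_msg_events(cfg)$end_x[1]
  log_step <- make_msg_log(cfg, function(t, ev) rep(ev1_end, length(t)))
  expect_equal(movement_onset(segment_responses(log_step)[[1]], cfg), 0)
})

test_that("programmed reaction times are recovered from simulated responses", {
  cfg <- msg_config(60, event_duration_s = 2, rng_seed = 17)
  log <- simulate_msg(cfg, player_model(reaction_time_ms = 300, seed = 18))
  sm <- msg_summary(log)
  onsets <- sm$responses$onset_ms
  # detection can only trail the true onset (5% of the distance must be
  # covered first), never anticipate it, and the mean recovers the programmed
  # latency within one sample period
  expect_true(all(onsets >= 300))
  expect_lte(abs(mean(onsets) - 300), 10)
})

test_that("success judgment agrees with a brute-force overlap check on 200 random responses", {
  checked <- 0
  for (k in 1:8) {
    cfg <- msg_config(60, event_duration_s = 2, distractor_fraction = 0.3,
                      paddle_halfwidth = stats::runif(1, 0.03, 0.1),
                      rng_seed = 400 + k)
    log <- simulate_msg(cfg, player_model(reaction_time_ms = 250,
                                          noise_sd = 0.03, miss_prob = 0.4,
                                          seed = 500 + k))
    rs <- segment_responses(log)
    for (r in rs) {
      expect_identical(judge_success(r, config = cfg),
                       oracle_success(log, log$events[log$events$event_id == r$event_id, ], cfg))
    }
    checked <- checked + length(rs)
  }
  expect_gte(checked, 200)
})

test_that("movement error matches direct averaging and its closed forms", {
  cfg <- msg_config(4, event_duration_s = 2, rng_seed = 23)
  ev <- schedule_msg_events(cfg)
  # jump to end_x at t = 500 ms and stay -> ME = 0 from onset
  jump <- function(t, evs) ifelse(t %% 2000 >= 500, ev$end_x[1 + t %/% 2000], 0.1)
  log <- make_msg_log(cfg, jump)
  rs <- segment_responses(log)
  on1 <- movement_onset(rs[[1]], cfg)
  expect_equal(movement_error(rs[[1]], config = cfg, onset_ms = on1), 0)
  # constant offset 0.1 after an onset forced at 0 -> ME = 0.1
  off_log <- make_msg_log(cfg, function(t, evs) ev$end_x[1 + t %/% 2000] + 0.1)
  off_rs <- segment_responses(off_log)
  expect_equal(movement_error(off_rs[[1]], config = cfg, onset_ms = 0), 0.1)
  # noisy simulated responses vs explicit loop oracle
  cfgn <- msg_config(30, event_duration_s = 2, rng_seed = 29)
  logn <- simulate_msg(cfgn, player_model(reaction_time_ms = 300,
                                          noise_sd = 0.02, seed = 30))
  for (r in segment_responses(logn)) {
    on <- movement_onset(r, cfgn)
    if (is.na(on)) {
      expect_true(is.na(movement_error(r, config = cfgn, onset_ms = on)))
    } else {
      expect_equal(movement_error(r, config = cfgn, onset_ms = on),
                   oracle_movement_error(r, on))
    }
  }
})

test_that("success rate counts targets only and is order-invariant", {
  cfg <- msg_config(60, event_duration_s = 2, distractor_fraction = 0.4,
                    rng_seed = 31)
  log <- simulate_msg(cfg, player_model(miss_prob = 0.5, seed = 32))
  sm <- msg_summary(log)
  expect_identical(sm$n_targets + sm$n_distractors, sm$n_events)
  expect_gte(sm$n_distractors, 1)
  # denominator is the target count, not the event count
  expect_equal(sm$success_rate_pct, 100 * sm$n_caught / sm$n_targets)
  # permuting the event table leaves SR unchanged
  permuted <- log
  set.seed(1)
  permuted$events <- permuted$events[sample(nrow(permuted$events)), ]
  expect_equal(msg_summary(permuted)$success_rate_pct, sm$success_rate_pct)
  # all-target log with no events caught vs all caught
  expect_error(msg_summary(make_msg_log(msg_config(2, event_duration_s = 2,
                                                   distractor_fraction = 1,
                                                   rng_seed = 2),
                                        function(t, ev) rep(0.5, length(t)))),
               "target event")
})

test_that("half of the targets caught gives a 50% success rate", {
  cfg <- msg_config(60, event_duration_s = 2, rng_seed = 37)
  ev <- schedule_msg_events(cfg)
  # park exactly at end_x for even events, far away for odd ones
  paddle <- function(t, evs) {
    i <- pmin(1 + t %/% 2000, nrow(ev))
    ifelse(i %% 2 == 0, ev$end_x[i], pmax(0, ev$end_x[i] - 0.5) + ifelse(ev$end_x[i] < 0.5, 0.5 + ev$end_x[i], 0))
  }
  # simpler: even events at end_x, odd events at the opposite screen edge
  paddle <- function(t, evs) {
    i <- pmin(1 + t %/% 2000, nrow(ev))
    ifelse(i %% 2 == 0, ev$end_x[i], ifelse(ev$end_x[i] < 0.5, 0.99, 0.01))
  }
  log <- make_msg_log(cfg, paddle)
  expect_equal(msg_summary(log)$success_rate_pct, 50)
  # all caught -> 100%
  log_all <- make_msg_log(cfg, function(t, evs) ev$end_x[pmin(1 + t %/% 2000, nrow(ev))])
  expect_equal(msg_summary(log_all)$success_rate_pct, 100)
})

test_that("movement time measures onset-to-stabilization within the catch window", {
  cfg <- msg_config(4, event_duration_s = 2, rng_seed = 41)
  ev <- schedule_msg_events(cfg)
  # ramp reaching the catch window at 800 ms, after onset at 300 ms
  paddle <- function(t, evs) {
    rel <- t %% 2000
    start <- if (ev$end_x[1] > 0.5) 0.1 else 0.9
    ifelse(rel < 300, start,
           start + pmin(1, (rel - 300) / 500) * (ev$end_x[1] - start))
  }
  log <- make_msg_log(cfg, paddle)
  r <- segment_responses(log)[[1]]
  on <- movement_onset(r, cfg)
  mt <- movement_time(r, config = cfg, onset_ms = on)
  # stabilizes when the ramp enters the window for good, i.e. when the
  # remaining distance falls below the catch half-width
  inside <- abs(r$paddle - ev$end_x[1]) <= cfg$paddle_halfwidth + cfg$object_radius
  expect_equal(mt, r$t_ms[max(which(!inside)) + 1] - on)
  # a paddle that never settles in the window has no movement time
  drift <- make_msg_log(cfg, function(t, evs) rep(0.5, length(t)))
  r2 <- segment_responses(drift)[[1]]
  if (abs(0.5 - ev$end_x[1]) > cfg$paddle_halfwidth + cfg$object_radius) {
    expect_true(is.na(movement_time(r2, config = cfg, onset_ms = 0)))
  }
})

test_that("per-direction movement variation uses the CT COV rule", {
  cfg <- msg_config(60, event_duration_s = 2,
                    trajectory_complexity = "diagonal", rng_seed = 43)
  log <- simulate_msg(cfg, player_model(reaction_time_ms = 250, seed = 44))
  sm <- msg_summary(log)
  expect_true(all(sm$per_direction$direction %in% c("diagonal-left", "diagonal-right")))
  big <- sm$per_direction[sm$per_direction$n >= 4, ]
  for (i in seq_len(nrow(big))) {
    grp <- sm$responses[sm$responses$direction == big$direction[i] &
                          sm$responses$kind == "target", ]
    expect_equal(big$amplitude_cov_pct[i],
                 100 * stats::sd(grp$peak_displacement) / mean(grp$peak_displacement))
  }
  # groups smaller than 4 responses report no COV
  small <- sm$per_direction[sm$per_direction$n < 4, ]
  expect_true(all(is.na(small$amplitude_cov_pct)))
})
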