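# Synthetic player: generates session logs with controllable impairment
# parameters so every metric is testable without patient data, and so
# parameter-recovery studies can validate the analysis chain. The model is a
# pure-delay + gain + additive-noise tracker: the simplest model whose
# parameters map one-to-one onto the performance measures (lag -> residual
# error, gain -> movement amplitude, noise -> variation).

#' Synthetic player model
#'
#' @param reaction_time_ms Mean appearance-to-onset latency for MSG events
#'   (ms).
#' @param reaction_time_sd_ms SD of the drawn reaction times (ms); draws are
#'   truncated at 0.
#' @param tracking_lag_ms Pure pursuit delay for CT tracking (ms).
#' @param gain Dimensionless multiplier on the required displacement (about
#'   the waveform centre for CT; toward the arrival position for MSG). 1 is
#'   a veridical response.
#' @param noise_sd SD of additive Gaussian position noise, normalized units;
#'   also used for the endpoint placement error of MSG responses.
#' @param miss_prob Probability that a target event elicits no adequate
#'   response. A "missed" event is simulated as an errant movement toward a
#'   random location outside the catch window (an inadequate response), not a
#'   resting paddle: a paddle parked at screen centre would still be caught
#'   by luck whenever a target happens to arrive nearby, which would break
#'   the identity SR = 1 - miss_prob that this parameter exists to provide.
#' @param max_speed Paddle speed cap in normalized units per second; MSG
#'   responses move along a minimum-time ramp bounded by this cap.
#' @param seed Integer seed; one RNG stream per simulated log, never the
#'   global stream.
#' @return A `rtp_player_model`.
#' @export
player_model <- function(reaction_time_ms = 300, reaction_time_sd_ms = 0,
                         tracking_lag_ms = 0, gain = 1, noise_sd = 0,
                         miss_prob = 0, max_speed = 2, seed = 1L) {
  p <- structure(list(
    reaction_time_ms = reaction_time_ms,
    reaction_time_sd_ms = reaction_time_sd_ms,
    tracking_lag_ms = tracking_lag_ms,
    gain = gain,
    noise_sd = noise_sd,
    miss_prob = miss_prob,
    max_speed = max_speed,
    seed = as.integer(seed)
  ), class = "rtp_player_model")
  for (f in c("reaction_time_ms", "reaction_time_sd_ms", "tracking_lag_ms",
              "gain", "noise_sd", "max_speed")) {
    check_number(p[[f]], f, min = 0)
  }
  check_number(p$miss_prob, "miss_prob", min = 0, max = 1)
  p
}

#' Simulate a cyclic-tracking trial
#'
#' The simulated paddle tracks the target with a pure delay, a gain applied
#' to the displacement about the waveform centre, and additive Gaussian
#' noise:
#' `paddle(t) = center + gain * (target(t - lag) - center) + e(t)`.
#' Deterministic given `(config, player$seed)`.
#'
#' @param config A CT `rtp_trial_config`.
#' @param player A [player_model()].
#' @param participant_id Participant identifier recorded in the log.
#' @return A validated CT `rtp_session`.
#' @export
simulate_ct <- function(config, player = player_model(),
                        participant_id = "sim") {
  validate_config(config)
  if (config$module_kind != "CT") {
    abort_validation("simulate_ct requires a CT configuration", "module_kind")
  }
  wave <- config_waveform(config)
  n <- n_samples(config)
  dt <- sample_dt_ms(config)
  t_ms <- as.integer(seq(0L, by = dt, length.out = n))
  target <- ct_target_position(wave, t_ms)
  lagged <- ct_target_position(wave, t_ms - player$tracking_lag_ms)
  noise <- with_rng(player$seed, stats::rnorm(n, 0, player$noise_sd))
  paddle <- wave$center + player$gain * (lagged - wave$center) + noise
  paddle <- pmin(1, pmax(0, paddle))
  samples <- tibble::tibble(
    t_ms = t_ms,
    paddle_pos = paddle,
    target_x = if (config$axis == "horizontal") target else rep(0.5, n),
    target_y = if (config$axis == "horizontal") rep(0.5, n) else target,
    event_id = rep(NA_integer_, n)
  )
  session_log(config, samples, participant_id = participant_id)
}

# Minimum-time ramp from `from` toward `to` bounded by the speed cap,
# evaluated at relative times `t_ms` after movement start.
ramp_position <- function(from, to, max_speed, t_ms) {
  travel_ms <- abs(to - from) / max_speed * 1000
  u <- if (travel_ms > 0) pmin(1, pmax(0, t_ms / travel_ms)) else as.numeric(t_ms >= 0)
  from + u * (to - from)
}

#' Simulate a motor-skill-game trial
#'
#' Generates the event schedule from the configuration, then synthesizes the
#' paddle trace event by event. For each target event, with probability
#' `1 - miss_prob` the paddle holds its position until a drawn reaction time,
#' then moves toward the object's arrival coordinate (scaled by `gain`, with
#' Gaussian endpoint error of SD `noise_sd`) along a minimum-time ramp
#' bounded by `max_speed`, and holds there. Missed target events produce an
#' errant ramp toward a random location outside the catch window. On
#' distractor events the paddle holds, moving away only if its resting
#' position would be struck. Per-sample Gaussian position noise (`noise_sd`)
#' is added to the whole trace. Deterministic given
#' `(config, player$seed)`.
#'
#' @inheritParams simulate_ct
#' @param config An MSG `rtp_trial_config`.
#' @return A validated MSG `rtp_session`.
#' @export
simulate_msg <- function(config, player = player_model(),
                         participant_id = "sim") {
  validate_config(config)
  if (config$module_kind != "MSG") {
    abort_validation("simulate_msg requires an MSG configuration", "module_kind")
  }
  events <- schedule_msg_events(config)
  n <- n_samples(config)
  dt <- sample_dt_ms(config)
  t_ms <- as.integer(seq(0L, by = dt, length.out = n))
  paddle <- rep(0.5, n)
  assigned <- rep(FALSE, n)
  event_id <- rep(NA_integer_, n)
  target_x <- rep(NA_real_, n)
  target_y <- rep(NA_real_, n)
  w <- catch_halfwidth(config)
  with_rng(player$seed, {
    pos <- 0.5
    for (i in seq_len(nrow(events))) {
      ev <- as.list(events[i, ])
      in_win <- t_ms >= ev$t_appear_ms - 1e-9 & t_ms < ev$t_disappear_ms - 1e-9
      if (!any(in_win)) next
      rel <- t_ms[in_win] - ev$t_appear_ms
      if (ev$kind == "target") {
        missed <- stats::runif(1) < player$miss_prob
        rt <- max(0, stats::rnorm(1, player$reaction_time_ms,
                                  player$reaction_time_sd_ms))
        goal_center <- if (missed) {
          # errant response: a wrong location well clear of the catch window
          g <- NA_real_
          for (k in 1:100) {
            g <- stats::runif(1, config$object_radius, 1 - config$object_radius)
            if (abs(g - ev$end_x) > w + 0.05) break
          }
          g
        } else {
          ev$end_x + stats::rnorm(1, 0, player$noise_sd)
        }
        goal <- pos + player$gain * (goal_center - pos)
        seg <- ifelse(rel < rt, pos,
                      ramp_position(pos, goal, player$max_speed, rel - rt))
      } else {
        # avoid the distractor: move away only if parked in its path
        if (abs(pos - ev$end_x) <= w + 0.02) {
          rt <- max(0, stats::rnorm(1, player$reaction_time_ms,
                                    player$reaction_time_sd_ms))
          safe <- if (ev$end_x < 0.5) min(1 - config$object_radius, ev$end_x + w + 0.1) else
            max(config$object_radius, ev$end_x - w - 0.1)
          seg <- ifelse(rel < rt, pos,
                        ramp_position(pos, safe, player$max_speed, rel - rt))
        } else {
          seg <- rep(pos, length(rel))
        }
      }
      paddle[in_win] <- seg
      assigned[in_win] <- TRUE
      pos <- seg[length(seg)]
      event_id[in_win] <- ev$event_id
      obj <- event_object_position(ev, config, t_ms[in_win])
      target_x[in_win] <- obj$x
      target_y[in_win] <- obj$y
    }
    paddle[!assigned] <- pos   # tail samples after the last scheduled event
    if (player$noise_sd > 0) {
      paddle <- paddle + stats::rnorm(n, 0, player$noise_sd)
    }
  })
  paddle <- pmin(1, pmax(0, paddle))
  samples <- tibble::tibble(
    t_ms = t_ms, paddle_pos = paddle,
    target_x = target_x, target_y = target_y, event_id = event_id
  )
  session_log(config, samples, events, participant_id = participant_id)
}
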