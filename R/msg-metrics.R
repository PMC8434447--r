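# Motor-skill-game performance measures. Each game event (object appearance
# to disappearance) yields one goal-directed game movement response; the
# responses are segmented, sorted by movement direction and scored for
# success rate (SR), movement onset time (MOT), movement time (MT), movement
# error (ME) and movement variation.

#' Segment an MSG log into per-event game movement responses
#'
#' Slices the sample stream on each event's `[t_appear_ms, t_disappear_ms)`
#' window (half-open, so back-to-back events share no sample) and attaches
#' the event context. Each response carries the paddle trajectory relative to
#' object appearance (time zero) through disappearance.
#'
#' @param log An MSG `rtp_session`.
#' @return A list of `rtp_response` objects, each with fields `event_id`,
#'   `kind`, `direction` (the event heading), `t_ms` (relative to
#'   appearance), `paddle` and `event` (the event row as a list).
#' @export
segment_responses <- function(log) {
  validate_session(log)
  cfg <- log$config
  if (cfg$module_kind != "MSG") {
    abort_validation("response segmentation is defined for MSG trials", "module_kind")
  }
  expected <- as.integer(round(cfg$event_duration_s * cfg$sample_rate_hz))
  t <- log$samples$t_ms
  lapply(seq_len(nrow(log$events)), function(i) {
    ev <- as.list(log$events[i, ])
    in_win <- t >= ev$t_appear_ms - 1e-9 & t < ev$t_disappear_ms - 1e-9
    if (sum(in_win) != expected) {
      abort_validation(sprintf(
        "event %d: window holds %d samples, expected %d",
        ev$event_id, sum(in_win), expected
      ), "samples")
    }
    structure(list(
      event_id = ev$event_id,
      kind = ev$kind,
      direction = ev$heading,
      t_ms = t[in_win] - ev$t_appear_ms,
      paddle = log$samples$paddle_pos[in_win],
      event = ev
    ), class = "rtp_response")
  })
}

# Baseline paddle position of a response: mean over the first `window_ms`.
# A multi-sample baseline is used instead of the single appearance sample
# because one noisy sample as reference destabilizes onset detection.
response_baseline <- function(response, window_ms = 50) {
  mean(response$paddle[response$t_ms <= window_ms - 1e-9])
}

#' Detect the movement onset of a game response
#'
#' Movement onset time (MOT, the tables' "response time") is the latency from
#' object appearance to the start of the paddle response. The detector is the
#' two-threshold (hysteresis) form standard in kinematic onset detection,
#' which keeps the 5%-of-distance onset rule while staying stable on noisy
#' pediatric/impaired traces:
#' * baseline = mean paddle position over the first 50 ms, and a robust
#'   (MAD) noise estimate from the first 100 ms;
#' * *confirmation*: movement is anchored at the first time the displacement
#'   from baseline exceeds `max(threshold_frac * distance, confirm_mult *
#'   noise)` and stays there for `sustain_ms` (`distance` = baseline to the
#'   object's arrival coordinate);
#' * *onset*: from the anchor, walk back to the last sample below the onset
#'   threshold `max(threshold_frac * distance, low_mult * noise)` and
#'   linearly interpolate the crossing time.
#'
#' At zero noise both thresholds collapse to the plain rule: first
#' displacement of 5% of the required distance, sustained `sustain_ms`.
#' Returns `NA` when no sustained displacement ever occurs -- the
#' no-movement contract, not an error.
#'
#' @param response A `rtp_response` from [segment_responses()].
#' @param config The trial configuration.
#' @param threshold_frac Fraction of the required movement distance that
#'   counts as onset (default 0.05).
#' @param sustain_ms Debounce: the confirmation displacement must persist
#'   this long (default 30 ms).
#' @param confirm_mult,low_mult Noise-floor multipliers for the confirmation
#'   and onset thresholds.
#' @return Onset in ms after appearance, or `NA_real_`.
#' @export
movement_onset <- function(response, config, threshold_frac = 0.05,
                           sustain_ms = 30, confirm_mult = 3,
                           low_mult = 1.28) {
  t <- response$t_ms
  x <- response$paddle
  if (length(x) < 2) return(NA_real_)
  b <- response_baseline(response)
  distance <- abs(response$event$end_x - b)
  disp <- abs(x - b)
  noise_hat <- stats::mad(x[t <= 100 - 1e-9])
  # a movement smaller than the noise floor cannot be detected: its plateau
  # never clears the confirmation threshold, so any "onset" would be a noise
  # artefact reported hundreds of ms late
  if (noise_hat > 0 && distance < confirm_mult * noise_hat) return(NA_real_)
  thr_confirm <- max(threshold_frac * distance, confirm_mult * noise_hat)
  thr_low <- max(threshold_frac * distance, low_mult * noise_hat)
  dt <- t[2] - t[1]
  sustain_n <- max(1L, as.integer(ceiling(sustain_ms / dt)) + 1L)
  above <- disp >= thr_confirm
  n <- length(above)
  anchor <- NA_integer_
  for (i in seq_len(n)) {
    j <- min(n, i + sustain_n - 1L)
    if (all(above[i:j])) {
      anchor <- i
      break
    }
  }
  if (is.na(anchor)) return(NA_real_)
  below <- which(disp[seq_len(anchor)] < thr_low)
  if (!length(below)) return(t[1])
  j <- max(below)
  if (j < n && disp[j + 1] > disp[j] && thr_low > 0) {
    frac <- (thr_low - disp[j]) / (disp[j + 1] - disp[j])
    t[j] + frac * dt
  } else {
    t[min(j + 1L, n)]
  }
}

# Catch window half-width: paddle halfwidth plus object radius.
catch_halfwidth <- function(config) config$paddle_halfwidth + config$object_radius

#' Judge the success of a game response
#'
#' Success is decided at the object's arrival sample (the last logged sample
#' of the event), not during transit, because the games catch objects at the
#' paddle line. A target is caught iff the paddle centre is within
#' `paddle_halfwidth + object_radius` of the object's arrival coordinate; a
#' distractor event is successful iff the paddle is NOT overlapping there.
#'
#' @param response A `rtp_response`.
#' @param event The event row (defaults to the response's own event).
#' @param config The trial configuration.
#' @return `TRUE` on success.
#' @export
judge_success <- function(response, event = response$event, config) {
  event <- as.list(event)
  arrival_pos <- response$paddle[length(response$paddle)]
  overlap <- abs(arrival_pos - event$end_x) <= catch_halfwidth(config)
  if (identical(event$kind, "distractor")) !overlap else overlap
}

#' Movement error of a game response
#'
#' The magnitude of movement error (ME) is the mean absolute difference
#' between the paddle position and the object's required interception
#' coordinate (`end_x`), over the samples from movement onset to event end,
#' in normalized screen units. Undefined (`NA`) when no onset was detected.
#'
#' @inheritParams judge_success
#' @param onset_ms Onset from [movement_onset()]; computed if missing.
#' @return Normalized units, or `NA_real_` when onset is `NA`.
#' @export
movement_error <- function(response, event = response$event, config,
                           onset_ms = NULL) {
  event <- as.list(event)
  if (is.null(onset_ms)) onset_ms <- movement_onset(response, config)
  if (is.na(onset_ms)) return(NA_real_)
  keep <- response$t_ms >= onset_ms - 1e-9
  mean(abs(response$paddle[keep] - event$end_x))
}

#' Movement time of a game response
#'
#' Time from movement onset to arrival stabilization, where stabilization is
#' the last time the paddle enters the catch window around the arrival
#' coordinate and remains inside it through event end. `NA` when there is no
#' onset or the paddle does not end the event inside the window.
#'
#' @inheritParams movement_error
#' @return Milliseconds, or `NA_real_`.
#' @export
movement_time <- function(response, event = response$event, config,
                          onset_ms = NULL) {
  event <- as.list(event)
  if (is.null(onset_ms)) onset_ms <- movement_onset(response, config)
  if (is.na(onset_ms)) return(NA_real_)
  inside <- abs(response$paddle - event$end_x) <= catch_halfwidth(config)
  n <- length(inside)
  if (!inside[n]) return(NA_real_)
  out <- which(!inside)
  stab_idx <- if (length(out)) max(out) + 1L else 1L
  max(0, response$t_ms[stab_idx] - onset_ms)
}

# Peak displacement of a response from its baseline (the movement-variation
# primitive).
peak_displacement <- function(response) {
  max(abs(response$paddle - response_baseline(response)))
}

#' Summarize a motor-skill-game trial
#'
#' Scores every game movement response and aggregates:
#' * `success_rate_pct`: 100 x caught targets / target events (distractors
#'   never enter the denominator);
#' * `mean_onset_ms`, `mean_movement_time_ms`, `mean_movement_error`: means
#'   over target responses with a detected onset;
#' * movement variation: per movement-direction group, the coefficient of
#'   variation of the per-response peak displacement (sample SD / mean, as a
#'   percent, reported for groups with at least `cov_min_responses`
#'   responses); `amplitude_cov_pct` averages the per-direction COVs.
#'
#' @param log An MSG `rtp_session` with at least one target event.
#' @param cov_min_responses Minimum responses per direction for a reported
#'   COV (same rule as the CT amplitude COV).
#' @param ... Passed to [movement_onset()].
#' @return A `rtp_msg_summary` list with the scalar fields above, counts
#'   (`n_events`, `n_targets`, `n_distractors`, `n_caught`), a
#'   `per_direction` tibble and a per-event `responses` tibble.
#' @export
msg_summary <- function(log, cov_min_responses = 4, ...) {
  responses <- segment_responses(log)
  cfg <- log$config
  if (!any(log$events$kind == "target")) {
    abort_validation("MSG summary requires at least one target event", "events")
  }
  rows <- lapply(responses, function(r) {
    onset <- movement_onset(r, cfg, ...)
    tibble::tibble(
      event_id = r$event_id,
      kind = r$kind,
      direction = r$direction,
      onset_ms = onset,
      movement_time_ms = movement_time(r, config = cfg, onset_ms = onset),
      caught = judge_success(r, config = cfg),
      movement_error = movement_error(r, config = cfg, onset_ms = onset),
      peak_displacement = peak_displacement(r)
    )
  })
  resp <- do.call(rbind, rows)
  targets <- resp[resp$kind == "target", ]
  n_targets <- nrow(targets)
  sr <- 100 * sum(targets$caught) / n_targets
  per_dir <- do.call(rbind, lapply(split(targets, targets$direction), function(g) {
    amp <- g$peak_displacement
    cov <- if (nrow(g) >= cov_min_responses && mean(amp) > 0) {
      100 * stats::sd(amp) / mean(amp)
    } else {
      NA_real_
    }
    tibble::tibble(
      direction = g$direction[1],
      n = nrow(g),
      success_rate_pct = 100 * sum(g$caught) / nrow(g),
      mean_onset_ms = mean(g$onset_ms, na.rm = TRUE),
      mean_movement_time_ms = mean(g$movement_time_ms, na.rm = TRUE),
      mean_movement_error = mean(g$movement_error, na.rm = TRUE),
      mean_peak_displacement = mean(amp),
      amplitude_cov_pct = cov
    )
  }))
  structure(list(
    success_rate_pct = sr,
    mean_onset_ms = mean(targets$onset_ms, na.rm = TRUE),
    mean_movement_time_ms = mean(targets$movement_time_ms, na.rm = TRUE),
    mean_movement_error = mean(targets$movement_error, na.rm = TRUE),
    amplitude_cov_pct = mean(per_dir$amplitude_cov_pct, na.rm = TRUE),
    n_events = nrow(resp),
    n_targets = n_targets,
    n_distractors = sum(resp$kind == "distractor"),
    n_caught = sum(targets$caught),
    per_direction = per_dir,
    responses = resp
  ), class = "rtp_msg_summary")
}

#' @export
print.rtp_msg_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<rtp_msg_summary> %d events (%d targets, %d distractors)\n",
           "  success rate %.1f%% (%d/%d caught)\n",
           "  mean onset %.0f ms, movement time %.0f ms, movement error %.4f\n",
           "  movement variation (COV of peak displacement) %.1f%%\n"),
    x$n_events, x$n_targets, x$n_distractors,
    x$success_rate_pct, x$n_caught, x$n_targets,
    x$mean_onset_ms, x$mean_movement_time_ms, x$mean_movement_error,
    x$amplitude_cov_pct
  ))
  invisible(x)
}

as_row.rtp_msg_summary <- function(x) {
  tibble::tibble(
    success_rate_pct = x$success_rate_pct,
    mean_onset_ms = x$mean_onset_ms,
    mean_movement_time_ms = x$mean_movement_time_ms,
    mean_movement_error = x$mean_movement_error,
    amplitude_cov_pct = x$amplitude_cov_pct,
    n_events = x$n_events,
    n_targets = x$n_targets,
    n_distractors = x$n_distractors
  )
}
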