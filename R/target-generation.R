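# Deterministic generation of CT target waveforms and MSG event schedules.

#' Cyclic-tracking target waveform
#'
#' The CT target oscillates sinusoidally about the screen centre:
#' `position(t) = center + amplitude * sin(2 * pi * frequency_hz * t + phase)`.
#' A sinusoid is the minimal smooth cyclic waveform with configurable
#' amplitude and frequency, and makes half-cycle segmentation analytic.
#'
#' @param amplitude Oscillation amplitude in normalized units.
#' @param frequency_hz Oscillation frequency in Hz.
#' @param axis `"horizontal"` or `"vertical"`: the screen axis of motion.
#' @param phase Phase offset in radians (default 0).
#' @param center Centre of oscillation in normalized units (default 0.5).
#' @return A `rtp_ct_waveform` object.
#' @export
ct_waveform <- function(amplitude, frequency_hz,
                        axis = c("horizontal", "vertical"),
                        phase = 0, center = 0.5) {
  axis <- match.arg(axis)
  check_number(amplitude, "amplitude", min = 0)
  check_number(frequency_hz, "frequency_hz", min = 1e-9)
  check_number(center, "center", min = 0, max = 1)
  if (center - amplitude < -1e-12 || center + amplitude > 1 + 1e-12) {
    abort_validation("waveform leaves the unit screen: |position - center| <= amplitude must stay in [0, 1]",
                     "amplitude")
  }
  structure(list(amplitude = amplitude, frequency_hz = frequency_hz,
                 axis = axis, phase = phase, center = center),
            class = "rtp_ct_waveform")
}

# Waveform implied by a CT trial configuration.
config_waveform <- function(config) {
  stopifnot(config$module_kind == "CT")
  ct_waveform(config$target_amplitude, config$target_frequency_hz, config$axis)
}

#' Evaluate the CT target position
#'
#' @param waveform A [ct_waveform()].
#' @param t_ms Time(s) since trial start in milliseconds (vectorized).
#' @return Normalized coordinate(s) along the waveform's axis.
#' @export
#' @examples
#' w <- ct_waveform(0.3, 0.25)
#' ct_target_position(w, c(0, 1000))  # centre, then centre + amplitude
ct_target_position <- function(waveform, t_ms) {
  t_s <- t_ms / 1000
  waveform$center +
    waveform$amplitude * sin(2 * pi * waveform$frequency_hz * t_s + waveform$phase)
}

#' Schedule the game events of an MSG trial
#'
#' Lays out `floor(duration_s / event_duration_s)` back-to-back,
#' non-overlapping game events. Each event's spawn position (the coordinate
#' along the paddle's axis at the opposite screen edge) is drawn uniformly
#' from the admissible range `[object_radius, 1 - object_radius]`; the event
#' is a distractor with probability `distractor_fraction`; under
#' `trajectory_complexity = "diagonal"` the arrival position is offset
#' laterally by 0.25 normalized units with a random sign (clipped to the
#' admissible range), otherwise the object crosses perpendicular to the
#' paddle line. The schedule is a deterministic function of the configuration
#' and its `rng_seed`.
#'
#' @param config An MSG `rtp_trial_config`.
#' @return A tibble of game events with columns `event_id, kind, t_appear_ms,
#'   t_disappear_ms, spawn_x, heading, end_x`.
#' @export
schedule_msg_events <- function(config) {
  validate_config(config)
  if (config$module_kind != "MSG") {
    abort_validation("event scheduling requires an MSG configuration", "module_kind")
  }
  if (config$event_duration_s > config$duration_s && config$duration_s > 0) {
    abort_validation("event_duration_s exceeds trial duration_s", "event_duration_s")
  }
  n <- floor(config$duration_s / config$event_duration_s)
  if (n == 0) return(event_schema())
  margin <- config$object_radius
  lo <- margin
  hi <- 1 - margin
  with_rng(config$rng_seed, {
    spawn_x <- stats::runif(n, lo, hi)
    is_distractor <- stats::runif(n) < config$distractor_fraction
    diag_sign <- sample(c(-1, 1), n, replace = TRUE)
  })
  if (config$trajectory_complexity == "diagonal") {
    end_x <- pmin(hi, pmax(lo, spawn_x + diag_sign * 0.25))
    heading <- ifelse(diag_sign < 0, "diagonal-left", "diagonal-right")
  } else {
    end_x <- spawn_x
    heading <- if (config$axis == "horizontal") "downward" else "rightward"
  }
  dur_ms <- config$event_duration_s * 1000
  tibble::tibble(
    event_id = seq_len(n),
    kind = ifelse(is_distractor, "distractor", "target"),
    t_appear_ms = (seq_len(n) - 1) * dur_ms,
    t_disappear_ms = seq_len(n) * dur_ms,
    spawn_x = spawn_x,
    heading = heading,
    end_x = end_x
  )
}

#' Position of a game object during its event
#'
#' Game objects move in a straight line from their spawn point on the far
#' screen edge to their arrival point on the paddle's axis line, reaching it
#' exactly at `t_disappear_ms`. Both screen coordinates are returned:
#' `along` is the coordinate on the paddle's movement axis (interpolated
#' `spawn_x` to `end_x`) and `across` the perpendicular travel coordinate
#' (0 to the paddle line at 0.95).
#'
#' @param event One event row (list or single-row data frame) from
#'   [schedule_msg_events()].
#' @param config The trial configuration.
#' @param t_ms Time(s) in ms; must lie within `[t_appear_ms, t_disappear_ms]`.
#' @return A tibble with columns `x` and `y` (normalized screen coordinates).
#' @export
event_object_position <- function(event, config, t_ms) {
  event <- as.list(event)
  if (any(t_ms < event$t_appear_ms - 1e-9 | t_ms > event$t_disappear_ms + 1e-9)) {
    abort_validation(sprintf(
      "t_ms outside event %d window [%g, %g]",
      event$event_id, event$t_appear_ms, event$t_disappear_ms
    ), "t_ms")
  }
  u <- (t_ms - event$t_appear_ms) / (event$t_disappear_ms - event$t_appear_ms)
  along <- event$spawn_x + u * (event$end_x - event$spawn_x)
  across <- u * rtp_paddle_line()
  if (config$axis == "horizontal") {
    tibble::tibble(x = along, y = across)
  } else {
    tibble::tibble(x = across, y = along)
  }
}
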