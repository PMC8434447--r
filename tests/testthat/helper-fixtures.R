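# Builders for small hand-made session logs and independent brute-force
# oracles used across the test files.

# CT log with an arbitrary paddle trace; `paddle` is a vector of length
# n_samples or a function of (t_ms, target).
make_ct_log <- function(config, paddle) {
  n <- round(config$duration_s * config$sample_rate_hz)
  dt <- 1000 / config$sample_rate_hz
  t_ms <- as.integer(seq(0, by = dt, length.out = n))
  wave <- ct_waveform(config$target_amplitude, config$target_frequency_hz,
                      config$axis)
  target <- ct_target_position(wave, t_ms)
  if (is.function(paddle)) paddle <- paddle(t_ms, target)
  samples <- tibble::tibble(
    t_ms = t_ms,
    paddle_pos = paddle,
    target_x = if (config$axis == "horizontal") target else rep(0.5, n),
    target_y = if (config$axis == "horizontal") rep(0.5, n) else target,
    event_id = rep(NA_integer_, n)
  )
  session_log(config, samples)
}

# MSG log with a caller-supplied paddle trace over the scheduled events.
make_msg_log <- function(config, paddle) {
  events <- schedule_msg_events(config)
  n <- round(config$duration_s * config$sample_rate_hz)
  dt <- 1000 / config$sample_rate_hz
  t_ms <- as.integer(seq(0, by = dt, length.out = n))
  if (is.function(paddle)) paddle <- paddle(t_ms, events)
  target_x <- rep(NA_real_, n)
  target_y <- rep(NA_real_, n)
  event_id <- rep(NA_integer_, n)
  for (i in seq_len(nrow(events))) {
    ev <- as.list(events[i, ])
    in_win <- t_ms >= ev$t_appear_ms & t_ms < ev$t_disappear_ms
    obj <- event_object_position(ev, config, t_ms[in_win])
    target_x[in_win] <- obj$x
    target_y[in_win] <- obj$y
    event_id[in_win] <- ev$event_id
  }
  samples <- tibble::tibble(t_ms = t_ms, paddle_pos = paddle,
                            target_x = target_x, target_y = target_y,
                            event_id = event_id)
  session_log(config, samples, events)
}

# Brute-force residual error: explicit per-sample loop, independent of the
# vectorized implementation.
oracle_residual <- function(log) {
  target <- if (log$config$axis == "horizontal") log$samples$target_x else log$samples$target_y
  out <- numeric(nrow(log$samples))
  for (i in seq_along(out)) {
    out[i] <- abs(target[i] - log$samples$paddle_pos[i])
  }
  out
}

# Brute-force half-cycle amplitudes: find extrema of the *sampled* target by
# local sign-change scanning (no analytic boundary formula), then take
# max - min of the paddle between consecutive extrema (closed windows: the
# turning-point sample belongs to both neighbours), with the trailing
# partial stretch to trial end appended.
oracle_half_cycle_amplitudes <- function(log) {
  target <- if (log$config$axis == "horizontal") log$samples$target_x else log$samples$target_y
  pad <- log$samples$paddle_pos
  d <- diff(target)
  ext <- which(diff(sign(d)) != 0) + 1L
  bounds <- c(ext, length(target))
  amps <- numeric(length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- bounds[i]:bounds[i + 1L]
    amps[i] <- max(pad[idx]) - min(pad[idx])
  }
  amps
}

# Brute-force success judgment: scan every sample of the event window for
# the last one and test overlap there.
oracle_success <- function(log, event_row, config) {
  ev <- as.list(event_row)
  sel <- which(log$samples$t_ms >= ev$t_appear_ms &
                 log$samples$t_ms < ev$t_disappear_ms)
  arrival <- sel[which.max(log$samples$t_ms[sel])]
  ov <- abs(log$samples$paddle_pos[arrival] - ev$end_x) <=
    config$paddle_halfwidth + config$object_radius
  if (ev$kind == "distractor") !ov else ov
}

# Brute-force movement error: explicit averaging loop from onset to event end.
oracle_movement_error <- function(response, onset_ms) {
  tot <- 0
  cnt <- 0
  for (i in seq_along(response$t_ms)) {
    if (response$t_ms[i] >= onset_ms) {
      tot <- tot + abs(response$paddle[i] - response$event$end_x)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}
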