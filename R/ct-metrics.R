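# Cyclic-tracking performance measures: residual error (TRE/ARE) and
# half-cycle amplitude variation (mean, SD, COV%), with the first two full
# target cycles excluded because subjects typically need a cycle or two to
# lock on to the moving target.

# Coordinate of the target along the tracked axis for a CT log.
ct_target_axis <- function(log) {
  if (log$config$axis == "horizontal") log$samples$target_x else log$samples$target_y
}

#' Per-sample residual tracking error
#'
#' For every logged sample, the residual error is the absolute difference
#' between the target position and the paddle position along the configured
#' movement axis, in normalized screen units. Absolute (not signed)
#' differences are used so the total cannot cancel across sides of the
#' target.
#'
#' @param log A CT `rtp_session`.
#' @return A tibble with columns `t_ms` and `error`.
#' @export
residual_error_series <- function(log) {
  validate_session(log)
  if (log$config$module_kind != "CT") {
    abort_validation("residual error is defined for CT trials", "module_kind")
  }
  target <- ct_target_axis(log)
  if (anyNA(target)) {
    abort_validation(sprintf(
      "missing target position at sample row %d", which(is.na(target))[1]
    ), "target")
  }
  tibble::tibble(t_ms = log$samples$t_ms,
                 error = abs(target - log$samples$paddle_pos))
}

# Half-cycle boundary times (ms) of the target sinusoid: consecutive extrema
# occur every 1/(2f) seconds starting from the first extremum at
# (pi/2 - phase)/(2 pi f). The trailing partial interval up to trial end is
# kept so a d-second trial contains 2*f*d half-cycles.
half_cycle_boundaries_ms <- function(config) {
  f <- config$target_frequency_hz
  first_s <- 1 / (4 * f)   # phase 0 waveform: first extremum at T/4
  starts_s <- seq(first_s, config$duration_s, by = 1 / (2 * f))
  starts_s <- starts_s[starts_s < config$duration_s - 1e-12]
  starts_s * 1000
}

#' Segment a CT trial into half-cycles of paddle movement
#'
#' Half-cycle boundaries are placed at consecutive extrema of the *target*
#' waveform (analytic for the sinusoid: every `1/(2f)` seconds from the first
#' extremum at a quarter period), not at detected paddle extrema -- the
#' target-based segmentation stays well defined for impaired, non-periodic
#' paddle motion. The movement amplitude of each half-cycle is the
#' peak-to-trough excursion (max - min) of the paddle position within the
#' interval. A perfect tracker of a target with amplitude A scores 2A in
#' every half-cycle.
#'
#' @param log A CT `rtp_session` covering at least 3 full target cycles (the
#'   two-cycle exclusion must leave something to analyze).
#' @return A tibble with columns `index`, `start_ms`, `end_ms`, `amplitude`
#'   and `complete` (`FALSE` for the trailing partial interval between the
#'   last extremum and trial end, which counts toward the segmentation but is
#'   not a full half-cycle of movement).
#' @export
segment_half_cycles <- function(log) {
  validate_session(log)
  cfg <- log$config
  if (cfg$module_kind != "CT") {
    abort_validation("half-cycle segmentation is defined for CT trials", "module_kind")
  }
  if (cfg$duration_s * cfg$target_frequency_hz < 3 - 1e-9) {
    abort_validation(sprintf(
      "trial covers %.2f target cycles; at least 3 are required",
      cfg$duration_s * cfg$target_frequency_hz
    ), "duration_s")
  }
  starts <- half_cycle_boundaries_ms(cfg)
  ends <- c(starts[-1], cfg$duration_s * 1000)
  full_ms <- 1000 / (2 * cfg$target_frequency_hz)
  t <- log$samples$t_ms
  pad <- log$samples$paddle_pos
  # closed windows: the boundary sample is the turning point and belongs to
  # both adjacent half-cycles, so each interval sees its full peak-to-trough
  amplitude <- vapply(seq_along(starts), function(i) {
    in_win <- t >= starts[i] - 1e-9 & t <= ends[i] + 1e-9
    if (!any(in_win)) return(NA_real_)
    max(pad[in_win]) - min(pad[in_win])
  }, numeric(1))
  tibble::tibble(index = seq_along(starts), start_ms = starts,
                 end_ms = ends, amplitude = amplitude,
                 complete = abs((ends - starts) - full_ms) < 1e-6)
}

#' Summarize a cyclic-tracking trial
#'
#' Computes the CT performance measures over the analysis window, which
#' excludes the first two full target cycles (it often takes a subject one or
#' two cycles to begin tracking):
#' * `total_residual_error` (TRE): sum of per-sample absolute residual
#'   errors, in normalized-unit-samples;
#' * `average_residual_error` (ARE): their mean, in normalized units;
#' * `mean_amplitude` / `sd_amplitude`: mean and sample (n-1) SD of the
#'   half-cycle movement amplitudes;
#' * `cov_percent`: amplitude coefficient of variation,
#'   `100 * sd_amplitude / mean_amplitude`.
#'
#' The COV is reported as `NA` (with `cov_note` saying why) when the mean
#' amplitude is zero or when fewer than `cov_min_cycles` half-cycles are
#' available.
#'
#' @param log A CT `rtp_session`.
#' @param cov_min_cycles Minimum analyzed half-cycles for a reported COV.
#' @return A `rtp_ct_summary` list with the fields above plus
#'   `n_cycles_analyzed` (analyzed half-cycles) and `n_samples_analyzed`.
#' @export
ct_summary <- function(log, cov_min_cycles = 4) {
  errs <- residual_error_series(log)
  cfg <- log$config
  half <- segment_half_cycles(log)
  excl_ms <- 2 / cfg$target_frequency_hz * 1000   # two full periods
  keep <- errs$t_ms >= excl_ms - 1e-9
  if (!any(keep)) {
    abort_validation("no samples remain after the two-cycle exclusion", "duration_s")
  }
  tre <- sum(errs$error[keep])
  are <- mean(errs$error[keep])
  # amplitude stats use complete (extremum-to-extremum) half-cycles only:
  # a trailing partial interval is not a half cycle of movement
  half_keep <- half[half$start_ms >= excl_ms - 1e-9 & half$complete &
                      !is.na(half$amplitude), ]
  n_cycles <- nrow(half_keep)
  mean_amp <- if (n_cycles > 0) mean(half_keep$amplitude) else NA_real_
  sd_amp <- if (n_cycles > 1) stats::sd(half_keep$amplitude) else NA_real_
  cov <- NA_real_
  cov_note <- NA_character_
  if (n_cycles < cov_min_cycles) {
    cov_note <- sprintf("COV not reported: %d half-cycles < required %d",
                        n_cycles, cov_min_cycles)
  } else if (!is.na(mean_amp) && mean_amp <= 0) {
    cov_note <- "COV undefined: mean amplitude is zero"
  } else {
    cov <- 100 * sd_amp / mean_amp
  }
  structure(list(
    total_residual_error = tre,
    average_residual_error = are,
    mean_amplitude = mean_amp,
    sd_amplitude = sd_amp,
    cov_percent = cov,
    cov_note = cov_note,
    n_cycles_analyzed = n_cycles,
    n_samples_analyzed = sum(keep)
  ), class = "rtp_ct_summary")
}

#' @export
print.rtp_ct_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<rtp_ct_summary>\n  TRE %.4f (ARE %.5f) over %d samples\n",
           "  amplitude mean %.4f, SD %.4f, COV %s%% over %d half-cycles\n"),
    x$total_residual_error, x$average_residual_error, x$n_samples_analyzed,
    x$mean_amplitude, x$sd_amplitude,
    ifelse(is.na(x$cov_percent), "NA", sprintf("%.2f", x$cov_percent)),
    x$n_cycles_analyzed
  ))
  if (!is.na(x$cov_note)) cat("  note:", x$cov_note, "\n")
  invisible(x)
}

# Flatten a CT summary for CSV export.
as_row.rtp_ct_summary <- function(x) {
  tibble::tibble(
    total_residual_error = x$total_residual_error,
    average_residual_error = x$average_residual_error,
    mean_amplitude = x$mean_amplitude,
    sd_amplitude = x$sd_amplitude,
    cov_percent = x$cov_percent,
    n_cycles_analyzed = x$n_cycles_analyzed,
    n_samples_analyzed = x$n_samples_analyzed
  )
}
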