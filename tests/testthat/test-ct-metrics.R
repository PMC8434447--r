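ct_cfg <- function(...) {
  ct_config(duration_s = 30, target_frequency_hz = 0.25,
            target_amplitude = 0.3, ...)
}

test_that("residual error series matches direct per-sample computation", {
  cfg <- ct_cfg()
  # paddle identical to target -> all zeros
  log <- make_ct_log(cfg, function(t, target) target)
  expect_equal(residual_error_series(log)$error, rep(0, 3000))
  # constant offset -> constant series
  log_off <- make_ct_log(cfg, function(t, target) target + 0.05)
  expect_equal(residual_error_series(log_off)$error, rep(0.05, 3000))
  # lagged noisy tracker vs explicit loop oracle
  log_lag <- simulate_ct(cfg, player_model(tracking_lag_ms = 180,
                                           noise_sd = 0.02, seed = 31))
  expect_equal(residual_error_series(log_lag)$error, oracle_residual(log_lag))
  # a missing target sample is an error
  broken <- log_lag
  broken$samples$target_x[100] <- NA_real_
  expect_error(residual_error_series(broken), "missing target position")
})

test_that("half-cycle segmentation counts 2*f*duration intervals with target-based boundaries", {
  cfg <- ct_cfg()  # 30 s at 0.25 Hz
  log <- make_ct_log(cfg, function(t, target) target)
  hc <- segment_half_cycles(log)
  expect_identical(nrow(hc), 15L)  # 30 s x 2 x 0.25 Hz
  # boundaries at consecutive target extrema: first at T/4 = 1 s, then every 2 s
  expect_equal(hc$start_ms, seq(1000, 29000, by = 2000))
  # perfect tracker scores peak-to-trough = 2A in every complete half-cycle
  expect_equal(hc$amplitude[hc$complete], rep(0.6, 14), tolerance = 1e-6)
  # motionless paddle scores 0
  hc0 <- segment_half_cycles(make_ct_log(cfg, function(t, target) rep(0.5, length(t))))
  expect_equal(hc0$amplitude, rep(0, 15))
  # fewer than 3 target cycles is an error
  short <- make_ct_log(ct_config(duration_s = 8, target_frequency_hz = 0.25),
                       function(t, target) target)
  expect_error(segment_half_cycles(short), "at least 3")
})

test_that("ct_summary applies the closed forms for offset trackers", {
  cfg <- ct_cfg()
  perfect <- ct_summary(make_ct_log(cfg, function(t, target) target))
  expect_equal(perfect$total_residual_error, 0)
  expect_equal(perfect$average_residual_error, 0)
  expect_equal(perfect$cov_percent, 0)

  # constant offset d over the N analyzed samples: TRE = N*d, ARE = d
  d <- 0.07
  off <- ct_summary(make_ct_log(cfg, function(t, target) target + d))
  n_analyzed <- sum(seq(0, by = 10, length.out = 3000) >= 8000)  # after 2 cycles
  expect_equal(off$n_samples_analyzed, n_analyzed)
  expect_equal(off$total_residual_error, n_analyzed * d)
  expect_equal(off$average_residual_error, d)

  # COV from the sample SD formula, against hand arithmetic
  amps <- c(0.4, 0.4, 0.2, 0.6)
  hand_sd <- sqrt(sum((amps - mean(amps))^2) / (length(amps) - 1))
  expect_equal(100 * hand_sd / 0.4, 100 * stats::sd(amps) / mean(amps))

  # motionless paddle: mean amplitude 0 -> COV flagged undefined
  flat <- ct_summary(make_ct_log(cfg, function(t, target) rep(0.5, length(t))))
  expect_true(is.na(flat$cov_percent))
  expect_match(flat$cov_note, "zero")
})

test_that("residual errors are invariant to a common translation of both traces", {
  cfg <- ct_config(duration_s = 30, target_frequency_hz = 0.25,
                   target_amplitude = 0.2)
  set.seed(11)
  jitter <- stats::rnorm(3000, 0, 0.03)
  base <- make_ct_log(cfg, function(t, target) target + jitter)
  shifted <- base
  shift <- 0.08
  shifted$samples$paddle_pos <- shifted$samples$paddle_pos + shift
  shifted$samples$target_x <- shifted$samples$target_x + shift
  expect_equal(residual_error_series(shifted)$error,
               residual_error_series(base)$error)
  expect_true(all(residual_error_series(base)$error >= 0))
})

test_that("corrupting the first two cycles leaves every summary field unchanged", {
  cfg <- ct_cfg()
  clean <- simulate_ct(cfg, player_model(tracking_lag_ms = 120,
                                         noise_sd = 0.015, seed = 77))
  corrupted <- clean
  excl <- which(corrupted$samples$t_ms < 2 / cfg$target_frequency_hz * 1000)
  set.seed(5)
  corrupted$samples$paddle_pos[excl] <- stats::runif(length(excl))
  a <- ct_summary(clean)
  b <- ct_summary(corrupted)
  expect_equal(unclass(b), unclass(a))
})

test_that("average residual error grows monotonically with programmed lag", {
  cfg <- ct_cfg()
  ares <- vapply(c(0, 100, 200, 350, 500), function(lag) {
    ct_summary(simulate_ct(cfg, player_model(tracking_lag_ms = lag, seed = 42)))$average_residual_error
  }, numeric(1))
  expect_true(all(diff(ares) >= 0))
})
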