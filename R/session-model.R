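# Session model: trial configurations, sample streams, game events, session
# logs and participant metadata, with invariant checking and lossless
# file readers/writers.
#
# Coordinate convention: the screen is the unit square [0,1] x [0,1], origin
# top-left, x rightward, y downward. The game paddle is one-dimensional: it
# moves along a fixed axis line (y = 0.95 for falling-object games with a
# horizontally moving paddle, x = 0.95 for the vertical counterpart) and its
# scalar position is recorded as `paddle_pos`. Pixel mapping is purely a
# presentation concern.

# Normalized coordinate of the paddle's fixed axis line; game objects travel
# from the opposite screen edge (coordinate 0) to this line.
rtp_paddle_line <- function() 0.95

#' Cyclic-tracking trial configuration
#'
#' Defines a cyclic tracking (CT) assessment trial: the player keeps the game
#' paddle overlapping a computer-controlled target that oscillates
#' sinusoidally with configurable amplitude and frequency along one screen
#' axis.
#'
#' @param duration_s Trial duration in seconds (>= 0). The product
#'   `duration_s * sample_rate_hz` must be a whole number of samples.
#' @param sample_rate_hz Logger sampling rate in Hz; the default 100 Hz gives
#'   10 ms sample spacing. `1000 / sample_rate_hz` must be a whole number of
#'   milliseconds.
#' @param axis `"horizontal"` (target moves left-right) or `"vertical"`
#'   (top-bottom).
#' @param target_amplitude Target oscillation amplitude in normalized screen
#'   units, in `[0, 0.5]` so the motion stays on screen around the centre.
#' @param target_frequency_hz Target oscillation frequency in Hz (> 0).
#' @param rng_seed Integer seed (unused for CT target generation, which is
#'   deterministic, but recorded for provenance).
#' @return A `rtp_trial_config` object with `module_kind = "CT"`.
#' @seealso [msg_config()], [simulate_ct()], [ct_summary()]
#' @export
#' @examples
#' cfg <- ct_config(duration_s = 30, target_amplitude = 0.3,
#'                  target_frequency_hz = 0.25)
ct_config <- function(duration_s = 30, sample_rate_hz = 100,
                      axis = c("horizontal", "vertical"),
                      target_amplitude = 0.3, target_frequency_hz = 0.25,
                      rng_seed = 1L) {
  axis <- match.arg(axis)
  cfg <- structure(list(
    module_kind = "CT",
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz,
    axis = axis,
    target_amplitude = target_amplitude,
    target_frequency_hz = target_frequency_hz,
    rng_seed = as.integer(rng_seed)
  ), class = "rtp_trial_config")
  validate_config(cfg)
  cfg
}

#' Motor-skill-game trial configuration
#'
#' Defines a motor skill game (MSG) assessment trial: game objects appear at
#' random locations on one screen edge and traverse to the paddle's axis line
#' in a fixed event duration; the player catches targets and avoids
#' distractors. A 60 s trial with 2 s events yields 30 goal-directed game
#' movement responses.
#'
#' @inheritParams ct_config
#' @param axis `"horizontal"`: the paddle moves horizontally along the line
#'   y = 0.95 and objects fall from the top edge; `"vertical"`: the paddle
#'   moves vertically at x = 0.95 and objects cross from the left edge.
#' @param event_duration_s Duration of each game event (object appearance to
#'   disappearance) in seconds (> 0).
#' @param paddle_halfwidth Half-width of the game paddle in normalized units;
#'   with `object_radius` it sets the movement-precision demand.
#' @param object_radius Radius of the game objects in normalized units; also
#'   the spawn margin keeping objects fully on screen.
#' @param distractor_fraction Probability in `[0, 1]` that an event is a
#'   distractor (an object that must be avoided) rather than a target.
#' @param trajectory_complexity `"straight"` (perpendicular crossing) or
#'   `"diagonal"` (a lateral offset of 0.25 normalized units, sign drawn per
#'   event).
#' @param object_speed Object travel speed in normalized units per second.
#'   Events have fixed duration and fixed travel (spawn edge to paddle line),
#'   so the speed is derived as `0.95 / event_duration_s`; supplying an
#'   inconsistent value is a validation error.
#' @param rng_seed Integer seed driving spawn locations, distractor draws and
#'   diagonal direction; the same seed and configuration always reproduce the
#'   identical event schedule.
#' @return A `rtp_trial_config` object with `module_kind = "MSG"`.
#' @seealso [schedule_msg_events()], [simulate_msg()], [msg_summary()]
#' @export
#' @examples
#' cfg <- msg_config(duration_s = 60, event_duration_s = 2, rng_seed = 7)
msg_config <- function(duration_s = 60, sample_rate_hz = 100,
                       axis = c("horizontal", "vertical"),
                       event_duration_s = 2, paddle_halfwidth = 0.05,
                       object_radius = 0.025, distractor_fraction = 0,
                       trajectory_complexity = c("straight", "diagonal"),
                       object_speed = NULL, rng_seed = 1L) {
  axis <- match.arg(axis)
  trajectory_complexity <- match.arg(trajectory_complexity)
  derived_speed <- rtp_paddle_line() / event_duration_s
  if (!is.null(object_speed) &&
      abs(object_speed - derived_speed) > 1e-9 * derived_speed) {
    abort_validation(sprintf(
      "field 'object_speed' = %g inconsistent with travel %g / event_duration_s %g",
      object_speed, rtp_paddle_line(), event_duration_s
    ), "object_speed")
  }
  cfg <- structure(list(
    module_kind = "MSG",
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz,
    axis = axis,
    event_duration_s = event_duration_s,
    paddle_halfwidth = paddle_halfwidth,
    object_radius = object_radius,
    distractor_fraction = distractor_fraction,
    trajectory_complexity = trajectory_complexity,
    object_speed = derived_speed,
    rng_seed = as.integer(rng_seed)
  ), class = "rtp_trial_config")
  validate_config(cfg)
  cfg
}

#' Validate a trial configuration
#'
#' Checks all configuration invariants: positive durations, a whole number of
#' samples (`duration_s * sample_rate_hz`), an integer millisecond sample
#' spacing, geometry that keeps every object inside the unit screen, and the
#' CT/MSG field separation. Called by the constructors; exported so logs read
#' from external front ends can be re-validated.
#'
#' @param config A `rtp_trial_config`.
#' @return The configuration, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "rtp_trial_config")) {
    abort_validation("not a trial configuration", "config")
  }
  check_choice(config$module_kind, "module_kind", c("CT", "MSG"))
  check_number(config$duration_s, "duration_s", min = 0)
  check_number(config$sample_rate_hz, "sample_rate_hz", min = 1)
  check_choice(config$axis, "axis", c("horizontal", "vertical"))
  n <- config$duration_s * config$sample_rate_hz
  if (abs(n - round(n)) > 1e-9) {
    abort_validation(sprintf(
      "duration_s * sample_rate_hz = %g is not a whole number of samples", n
    ), "duration_s")
  }
  dt <- 1000 / config$sample_rate_hz
  if (abs(dt - round(dt)) > 1e-9) {
    abort_validation(sprintf(
      "1000 / sample_rate_hz = %g ms is not an integer sample spacing", dt
    ), "sample_rate_hz")
  }
  if (config$module_kind == "CT") {
    check_number(config$target_amplitude, "target_amplitude", min = 0, max = 0.5)
    check_number(config$target_frequency_hz, "target_frequency_hz", min = 1e-9)
    if (!is.null(config$event_duration_s)) {
      abort_validation("MSG field 'event_duration_s' set on a CT config",
                       "event_duration_s")
    }
  } else {
    check_number(config$event_duration_s, "event_duration_s", min = 1e-9)
    check_number(config$paddle_halfwidth, "paddle_halfwidth", min = 1e-9, max = 0.5)
    check_number(config$object_radius, "object_radius", min = 1e-9, max = 0.25)
    check_number(config$distractor_fraction, "distractor_fraction", min = 0, max = 1)
    check_choice(config$trajectory_complexity, "trajectory_complexity",
                 c("straight", "diagonal"))
    if (!is.null(config$target_frequency_hz)) {
      abort_validation("CT field 'target_frequency_hz' set on an MSG config",
                       "target_frequency_hz")
    }
  }
  invisible(config)
}

# Millisecond sample spacing of a config.
sample_dt_ms <- function(config) as.integer(round(1000 / config$sample_rate_hz))

# Number of samples in a full trial.
n_samples <- function(config) as.integer(round(config$duration_s * config$sample_rate_hz))

# Canonical empty / typed event table.
event_schema <- function() {
  tibble::tibble(
    event_id = integer(),
    kind = character(),
    t_appear_ms = numeric(),
    t_disappear_ms = numeric(),
    spawn_x = numeric(),
    heading = character(),
    end_x = numeric()
  )
}

as_event_table <- function(df) {
  schema <- event_schema()
  if (is.null(df) || (is.list(df) && length(df) == 0L) ||
      (is.data.frame(df) && nrow(df) == 0L)) {
    return(schema)
  }
  df <- tibble::as_tibble(df)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    abort_validation(paste("event table missing columns:",
                           paste(missing, collapse = ", ")), "events")
  }
  df <- df[names(schema)]
  df$event_id <- as.integer(df$event_id)
  df$t_appear_ms <- as.numeric(df$t_appear_ms)
  df$t_disappear_ms <- as.numeric(df$t_disappear_ms)
  df$spawn_x <- as.numeric(df$spawn_x)
  df$end_x <- as.numeric(df$end_x)
  df$kind <- as.character(df$kind)
  df$heading <- as.character(df$heading)
  df
}

sample_schema <- function() {
  tibble::tibble(
    t_ms = integer(),
    paddle_pos = numeric(),
    target_x = numeric(),
    target_y = numeric(),
    event_id = integer()
  )
}

#' Assemble a session log
#'
#' Binds a trial configuration, the 100 Hz sample stream and the game-event
#' stream of one assessment trial into a validated session log, the unit of
#' analysis for all performance metrics.
#'
#' @param config A `rtp_trial_config` from [ct_config()] or [msg_config()].
#' @param samples Data frame with columns `t_ms` (integer ms, strictly
#'   increasing at the configured spacing), `paddle_pos`, `target_x`,
#'   `target_y` (normalized coordinates, `NA` between events) and `event_id`
#'   (integer or `NA`).
#' @param events Data frame of game events (see [schedule_msg_events()]);
#'   empty for CT trials.
#' @param participant_id Participant identifier string.
#' @return A validated `rtp_session` object.
#' @export
session_log <- function(config, samples, events = event_schema(),
                        participant_id = "anonymous") {
  samples <- tibble::as_tibble(samples)
  extra <- setdiff(names(samples), names(sample_schema()))
  if (length(extra)) {
    abort_validation(paste("unknown sample columns:",
                           paste(extra, collapse = ", ")), "samples")
  }
  missing <- setdiff(names(sample_schema()), names(samples))
  if (length(missing)) {
    abort_validation(paste("sample table missing columns:",
                           paste(missing, collapse = ", ")), "samples")
  }
  samples <- samples[names(sample_schema())]
  samples$t_ms <- as.integer(samples$t_ms)
  samples$event_id <- as.integer(samples$event_id)
  log <- structure(list(
    config = config,
    participant_id = as.character(participant_id),
    samples = samples,
    events = as_event_table(events)
  ), class = "rtp_session")
  validate_session(log)
  log
}

#' Validate a session log
#'
#' Enforces the structural invariants of a session log: sample count equal to
#' `duration_s * sample_rate_hz`, strictly increasing timestamps at the
#' configured spacing, every referenced `event_id` present in the event table,
#' samples tagged with an event only inside that event's time window, and
#' event windows of exactly the configured duration.
#'
#' @param log A `rtp_session`.
#' @return The log, invisibly; errors name the field or row at fault.
#' @export
validate_session <- function(log) {
  if (!inherits(log, "rtp_session")) abort_validation("not a session log", "log")
  validate_config(log$config)
  cfg <- log$config
  s <- log$samples
  expected_n <- n_samples(cfg)
  if (nrow(s) != expected_n) {
    abort_validation(sprintf(
      "sample count %d != duration_s * sample_rate_hz = %d", nrow(s), expected_n
    ), "samples")
  }
  if (nrow(s) > 0) {
    dt <- sample_dt_ms(cfg)
    expect_t <- as.integer(seq(0L, by = dt, length.out = nrow(s)))
    bad <- which(s$t_ms != expect_t)
    if (length(bad)) {
      abort_validation(sprintf(
        "sample row %d: t_ms = %d, expected %d (spacing %d ms from 0)",
        bad[1], s$t_ms[bad[1]], expect_t[bad[1]], dt
      ), "t_ms")
    }
  }
  ev <- log$events
  if (nrow(ev) > 0) {
    if (anyDuplicated(ev$event_id)) {
      abort_validation("duplicated event_id in event table", "event_id")
    }
    span <- ev$t_disappear_ms - ev$t_appear_ms
    if (cfg$module_kind == "MSG") {
      bad <- which(abs(span - cfg$event_duration_s * 1000) > 1e-6)
      if (length(bad)) {
        abort_validation(sprintf(
          "event %d: window %g ms != event_duration_s * 1000 = %g",
          ev$event_id[bad[1]], span[bad[1]], cfg$event_duration_s * 1000
        ), "events")
      }
    }
    if (any(ev$spawn_x < 0 | ev$spawn_x > 1 | ev$end_x < 0 | ev$end_x > 1)) {
      abort_validation("event spawn/end position outside [0, 1]", "events")
    }
  }
  ref <- s$event_id[!is.na(s$event_id)]
  if (length(ref)) {
    unknown <- setdiff(unique(ref), ev$event_id)
    if (length(unknown)) {
      abort_validation(sprintf(
        "sample references unknown event_id %d", unknown[1]
      ), "event_id")
    }
    idx <- match(s$event_id, ev$event_id)
    tagged <- which(!is.na(idx))
    outside <- tagged[s$t_ms[tagged] < ev$t_appear_ms[idx[tagged]] |
                        s$t_ms[tagged] > ev$t_disappear_ms[idx[tagged]]]
    if (length(outside)) {
      abort_validation(sprintf(
        "sample row %d: t_ms %d outside window of event %d",
        outside[1], s$t_ms[outside[1]], s$event_id[outside[1]]
      ), "event_id")
    }
  }
  invisible(log)
}

#' @export
print.rtp_session <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<rtp_session> %s trial, %gs @ %g Hz, %d samples, %d events, participant '%s'\n",
    cfg$module_kind, cfg$duration_s, cfg$sample_rate_hz,
    nrow(x$samples), nrow(x$events), x$participant_id
  ))
  invisible(x)
}

session_stem <- function(path) sub("\\.(json|csv)$", "", path)

#' Write a session log to disk
#'
#' Serializes a session log as a JSON header (`<stem>.json`: configuration,
#' participant, event stream) plus a CSV sample table (`<stem>.csv`: columns
#' `t_ms, paddle_pos, target_x, target_y, event_id`). The dialect is UTF-8,
#' comma-separated, `.` decimal, mandatory header row; coordinates absent
#' between events are written as empty fields. Doubles are written with 17
#' significant digits so that [read_session()] round-trips losslessly.
#'
#' @param log A validated `rtp_session`.
#' @param path Output path; a trailing `.json` or `.csv` is stripped and both
#'   files are written next to each other.
#' @return The JSON header path, invisibly.
#' @export
write_session <- function(log, path) {
  validate_session(log)
  stem <- session_stem(path)
  header <- list(
    format = "rtp-session",
    version = 1L,
    participant_id = log$participant_id,
    config = unclass(log$config),
    events = log$events
  )
  # digits = I(17): 17 *significant* digits round-trip IEEE doubles exactly
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = I(17), dataframe = "rows", na = "null",
                       pretty = TRUE)
  s <- log$samples
  lines <- c(
    "t_ms,paddle_pos,target_x,target_y,event_id",
    if (nrow(s) > 0) {
      paste(
        s$t_ms,
        fmt_num(s$paddle_pos),
        fmt_num(s$target_x),
        fmt_num(s$target_y),
        ifelse(is.na(s$event_id), "", as.character(s$event_id)),
        sep = ","
      )
    }
  )
  con <- file(paste0(stem, ".csv"), open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(paste0(stem, ".json"))
}

#' Read a session log from disk
#'
#' Reads and validates a session written by [write_session()] (or by any
#' external game front end emitting the same dialect). Non-monotone or
#' misaligned timestamps, unknown columns and malformed headers are rejected
#' with the offending row or field named.
#'
#' @param path Path to the `.json` header or the bare stem.
#' @return A validated `rtp_session`.
#' @export
read_session <- function(path) {
  stem <- session_stem(path)
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  if (!file.exists(json_path)) {
    abort_validation(paste("missing session header:", json_path), "path")
  }
  if (!file.exists(csv_path)) {
    abort_validation(paste("missing session sample table:", csv_path), "path")
  }
  header <- tryCatch(
    jsonlite::read_json(json_path, simplifyVector = TRUE),
    error = function(e) abort_validation(
      paste("malformed session header:", conditionMessage(e)), "header")
  )
  if (!identical(header$format, "rtp-session")) {
    abort_validation("malformed session header: not an rtp-session file", "format")
  }
  cfg_list <- header$config
  config <- if (identical(cfg_list$module_kind, "CT")) {
    ct_config(
      duration_s = cfg_list$duration_s,
      sample_rate_hz = cfg_list$sample_rate_hz,
      axis = cfg_list$axis,
      target_amplitude = cfg_list$target_amplitude,
      target_frequency_hz = cfg_list$target_frequency_hz,
      rng_seed = cfg_list$rng_seed
    )
  } else if (identical(cfg_list$module_kind, "MSG")) {
    msg_config(
      duration_s = cfg_list$duration_s,
      sample_rate_hz = cfg_list$sample_rate_hz,
      axis = cfg_list$axis,
      event_duration_s = cfg_list$event_duration_s,
      paddle_halfwidth = cfg_list$paddle_halfwidth,
      object_radius = cfg_list$object_radius,
      distractor_fraction = cfg_list$distractor_fraction,
      trajectory_complexity = cfg_list$trajectory_complexity,
      rng_seed = cfg_list$rng_seed
    )
  } else {
    abort_validation("malformed session header: unknown module_kind", "module_kind")
  }
  first <- readLines(csv_path, n = 1L)
  if (!identical(first, "t_ms,paddle_pos,target_x,target_y,event_id")) {
    got <- strsplit(first, ",", fixed = TRUE)[[1]]
    unknown <- setdiff(got, c("t_ms", "paddle_pos", "target_x", "target_y", "event_id"))
    if (length(unknown)) {
      abort_validation(paste("unknown sample columns:",
                             paste(unknown, collapse = ", ")), "samples")
    }
    abort_validation("sample table header row malformed or missing", "samples")
  }
  samples <- utils::read.csv(
    csv_path,
    colClasses = c(t_ms = "integer", paddle_pos = "numeric",
                   target_x = "numeric", target_y = "numeric",
                   event_id = "integer"),
    na.strings = ""
  )
  if (nrow(samples) > 1) {
    reg <- which(diff(samples$t_ms) <= 0)
    if (length(reg)) {
      abort_validation(sprintf(
        "timestamp regression at sample row %d: t_ms %d follows %d",
        reg[1] + 1L, samples$t_ms[reg[1] + 1L], samples$t_ms[reg[1]]
      ), "t_ms")
    }
  }
  session_log(config, samples, as_event_table(header$events),
              participant_id = header$participant_id %||% "anonymous")
}

#' Read or write a participant metadata table
#'
#' Participants files are CSVs with columns `id, age_years, gender, gmfcs,
#' macs`. The Gross Motor Function Classification System (GMFCS) and Manual
#' Ability Classification System (MACS) levels are restricted to I-III, the
#' platform's inclusion range.
#'
#' @param path CSV file path.
#' @return `read_participants()` returns a validated tibble.
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("id", "age_years", "gender", "gmfcs", "macs")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_validation(paste("participants file missing columns:",
                           paste(missing, collapse = ", ")), "participants")
  }
  df <- tibble::as_tibble(df[required])
  df$age_years <- as.numeric(df$age_years)
  validate_participants(df)
  df
}

#' @rdname read_participants
#' @param participants Data frame with the columns above.
#' @export
write_participants <- function(participants, path) {
  validate_participants(participants)
  utils::write.csv(participants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_participants <- function(df) {
  if (any(!df$gender %in% c("M", "F"))) {
    abort_validation("gender must be M or F", "gender")
  }
  for (col in c("gmfcs", "macs")) {
    if (any(!df[[col]] %in% c("I", "II", "III"))) {
      abort_validation(sprintf("%s level outside I-III", col), col)
    }
  }
  if (any(is.na(df$age_years) | df$age_years <= 0)) {
    abort_validation("age_years must be positive", "age_years")
  }
  invisible(df)
}
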