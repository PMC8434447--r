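# Trajectory plotting helpers (ggplot2, Suggests-only).

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_validation("plotting requires the ggplot2 package")
  }
}

#' Plot a cyclic-tracking trial
#'
#' Synchronous traces of the target and paddle positions over time, the
#' standard visual check of tracking overlap quality.
#'
#' @param log A CT `rtp_session`.
#' @return A ggplot object.
#' @export
plot_ct_trial <- function(log) {
  require_ggplot()
  target <- ct_target_axis(log)
  df <- rbind(
    data.frame(t_s = log$samples$t_ms / 1000, position = target, trace = "target"),
    data.frame(t_s = log$samples$t_ms / 1000, position = log$samples$paddle_pos,
               trace = "paddle")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = t_s, y = position,
                                   colour = trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized position",
                  title = "Cyclic tracking trial") +
    ggplot2::ylim(0, 1)
}

#' Overlay segmented game movement responses by direction
#'
#' Reproduces the standard overlay view of a motor-skill-game trial: every
#' response's paddle trajectory from object appearance (time zero) to
#' disappearance, grouped by movement direction.
#'
#' @param log An MSG `rtp_session`.
#' @return A ggplot object faceted by direction.
#' @export
plot_msg_responses <- function(log) {
  require_ggplot()
  responses <- segment_responses(log)
  df <- do.call(rbind, lapply(responses, function(r) {
    data.frame(t_s = r$t_ms / 1000, paddle = r$paddle,
               event = r$event_id, direction = r$direction, kind = r$kind)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = t_s, y = paddle,
                                   group = event, colour = kind)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "time from appearance (s)", y = "paddle position",
                  title = "Segmented game movement responses")
}
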