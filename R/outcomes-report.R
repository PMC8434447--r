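# Pre/post outcome arithmetic (integer percent-change tables, group
# averages) and test-retest reliability (ICC, SEM, MDC).

#' Integer percent change and percent reduction
#'
#' `percent_change()` is `100 * (post - pre) / pre`; `percent_reduction()` is
#' its negation, `100 * (pre - post) / pre`, the convention used when
#' improvements (e.g. shorter response times) are printed with positive sign.
#' Both round half away from zero to integer percent, the rounding that
#' reproduces every verifiable printed outcome-table cell. Before rounding
#' the two are exact negatives of each other.
#'
#' @param pre,post Numeric vectors (recycled); `pre` must be nonzero.
#' @param round Round to integer percent (default `TRUE`).
#' @return Numeric vector; `NA` with a warning where `pre == 0`.
#' @export
#' @examples
#' percent_change(45, 87)     # 93
#' percent_reduction(830, 680) # 18
percent_change <- function(pre, post, round = TRUE) {
  raw <- ifelse(pre == 0, NA_real_, 100 * (post - pre) / pre)
  if (anyNA(raw) && any(pre == 0)) {
    warning("percent change undefined where pre == 0; flagged as NA")
  }
  if (round) round_half_away(raw) else raw
}

#' @rdname percent_change
#' @export
percent_reduction <- function(pre, post, round = TRUE) {
  raw <- ifelse(pre == 0, NA_real_, 100 * (pre - post) / pre)
  if (anyNA(raw) && any(pre == 0)) {
    warning("percent reduction undefined where pre == 0; flagged as NA")
  }
  if (round) round_half_away(raw) else raw
}

#' Group average of integer percent values
#'
#' The rounded arithmetic mean of per-participant percent changes, as printed
#' in the outcome tables' Average row.
#'
#' @param values Non-empty numeric vector (NAs dropped with a warning).
#' @return A single integer-valued number.
#' @export
group_average <- function(values) {
  if (length(values) == 0) abort_validation("empty value list", "values")
  if (anyNA(values)) {
    warning("dropping NA percent values from the group average")
    values <- values[!is.na(values)]
  }
  round_half_away(mean(values))
}

#' Build a pre/post outcome table
#'
#' Matches participants across a pre- and a post-intervention set of
#' summaries, averages each participant's measure over movement directions
#' (tasks are scored as the average of the two practiced directions, e.g.
#' forward and backward rolling), and tabulates pre, post and integer percent
#' change per participant plus the group-average change.
#'
#' @param pre_summaries,post_summaries Data frames with columns
#'   `participant_id`, `value` and optionally `direction` (averaged out).
#' @param measure Label for the measure (e.g. `"success_rate_pct"`).
#' @param change `"signed"` for [percent_change()] or `"reduction"` for
#'   [percent_reduction()] (used for latency measures printed as positive
#'   reductions).
#' @return A `rtp_outcome_table`: list with `rows` (tibble `participant_id,
#'   pre, post, percent_change`), `average`, `measure`, `change`.
#' @export
build_outcome_table <- function(pre_summaries, post_summaries, measure = "value",
                                change = c("signed", "reduction")) {
  change <- match.arg(change)
  collapse <- function(df, label) {
    if (!all(c("participant_id", "value") %in% names(df))) {
      abort_validation(sprintf("%s summaries need participant_id and value columns",
                               label), label)
    }
    agg <- stats::aggregate(value ~ participant_id, data = df, FUN = mean)
    tibble::as_tibble(agg)
  }
  pre <- collapse(pre_summaries, "pre")
  post <- collapse(post_summaries, "post")
  unmatched <- c(setdiff(pre$participant_id, post$participant_id),
                 setdiff(post$participant_id, pre$participant_id))
  if (length(unmatched)) {
    abort_validation(paste("unmatched participant id:", unmatched[1]),
                     "participant_id")
  }
  m <- merge(pre, post, by = "participant_id", suffixes = c("_pre", "_post"))
  m <- m[order(match(m$participant_id, pre$participant_id)), ]
  pc <- if (change == "signed") {
    percent_change(m$value_pre, m$value_post)
  } else {
    percent_reduction(m$value_pre, m$value_post)
  }
  rows <- tibble::tibble(
    participant_id = m$participant_id,
    pre = m$value_pre,
    post = m$value_post,
    percent_change = pc
  )
  structure(list(
    rows = rows,
    average = group_average(pc),
    measure = measure,
    change = change
  ), class = "rtp_outcome_table")
}

#' @export
print.rtp_outcome_table <- function(x, ...) {
  cat(sprintf("<rtp_outcome_table> measure '%s' (%s percent change)\n",
              x$measure, x$change))
  print(x$rows)
  cat(sprintf("Average percent change: %d\n", as.integer(x$average)))
  invisible(x)
}

#' Test-retest reliability: ICC(2,1), SEM and MDC
#'
#' Computes the two-way random-effects, absolute-agreement, single-measure
#' intraclass correlation coefficient ICC(2,1) from the standard
#' variance-components decomposition of the subject x session score table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with MSR/MSC/MSE the rows (subjects), columns (sessions) and error mean
#' squares. The standard error of measurement is
#' `SEM = SD * sqrt(1 - ICC)` (SD over all scores), and the minimal
#' detectable change at the 95% level is `MDC = 1.96 * sqrt(2) * SEM`,
#' also expressed as a percent of the grand mean.
#'
#' @param session1_scores,session2_scores Paired score vectors from the two
#'   test occasions (same subjects, same order), length >= 3.
#' @return A `rtp_reliability` list: `icc`, `sem`, `mdc`, `mdc_pct_of_mean`,
#'   `n`, and `degenerate` (TRUE when the score table has zero total
#'   variance, in which case `icc` is `NA`).
#' @export
icc_test_retest <- function(session1_scores, session2_scores) {
  x1 <- as.numeric(session1_scores)
  x2 <- as.numeric(session2_scores)
  if (length(x1) != length(x2)) {
    abort_validation("sessions have different numbers of scores", "scores")
  }
  n <- length(x1)
  if (n < 3) abort_validation("at least 3 paired scores are required", "scores")
  if (anyNA(x1) || anyNA(x2)) abort_validation("missing scores", "scores")
  scores <- cbind(x1, x2)
  k <- 2L
  grand <- mean(scores)
  total_ss <- sum((scores - grand)^2)
  if (total_ss <= .Machine$double.eps * n) {
    return(structure(list(
      icc = NA_real_, sem = 0, mdc = 0,
      mdc_pct_of_mean = if (grand != 0) 0 else NA_real_,
      n = n, degenerate = TRUE
    ), class = "rtp_reliability"))
  }
  row_means <- rowMeans(scores)
  col_means <- colMeans(scores)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- total_ss - k * sum((row_means - grand)^2) - n * sum((col_means - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  sd_all <- stats::sd(as.vector(scores))
  sem <- sd_all * sqrt(max(0, 1 - icc))
  mdc <- 1.96 * sqrt(2) * sem
  structure(list(
    icc = icc,
    sem = sem,
    mdc = mdc,
    mdc_pct_of_mean = if (grand != 0) 100 * mdc / abs(grand) else NA_real_,
    n = n,
    degenerate = FALSE
  ), class = "rtp_reliability")
}

#' @export
print.rtp_reliability <- function(x, ...) {
  if (x$degenerate) {
    cat("<rtp_reliability> degenerate: zero total variance in the score table\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<rtp_reliability> n = %d paired scores\n  ICC(2,1) %.3f, SEM %.4g, MDC95 %.4g (%.1f%% of mean)\n",
    x$n, x$icc, x$sem, x$mdc, x$mdc_pct_of_mean
  ))
  invisible(x)
}
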