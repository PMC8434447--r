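test_that("integer percent change reproduces the printed worked examples", {
  expect_equal(percent_change(45, 87), 93)
  expect_equal(percent_change(30, 84), 180)
  expect_equal(percent_change(44, 50), 14)
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_reduction(830, 680), 18)
  expect_equal(percent_reduction(650, 526), 19)
  expect_equal(percent_reduction(123, 123), 0)
  # pre = 0 is flagged, not computed
  expect_warning(out <- percent_change(0, 10), "pre == 0")
  expect_true(is.na(out))
})

test_that("percent change and percent reduction are exact negatives before rounding", {
  set.seed(19)
  pre <- stats::runif(200, 1, 1000)
  post <- stats::runif(200, 1, 1000)
  expect_equal(percent_change(pre, post, round = FALSE),
               -percent_reduction(pre, post, round = FALSE))
})

test_that("group averages round half away from zero like the printed footers", {
  expect_equal(group_average(c(93, 11, 22, 0, 180, 82)), 65)
  expect_equal(group_average(c(57, 66, 33, 34, 75, 0)), 44)
  expect_equal(group_average(c(0)), 0)
  expect_equal(group_average(c(4, 34, 18, 18, 19, 12)), 18)  # mean 17.5 rounds up
  expect_equal(group_average(c(-6, -18, 4, -8, -28, -23)), -13)
  expect_error(group_average(numeric(0)), "empty")
})

test_that("outcome tables average directions, match ids and recompute changes", {
  pre <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 2),
    direction = rep(c("leftward", "rightward"), 2),
    value = c(40, 50, 60, 70)
  )
  post <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 2),
    direction = rep(c("leftward", "rightward"), 2),
    value = c(80, 100, 63, 67)
  )
  tab <- build_outcome_table(pre, post, measure = "sr")
  # direction-averaged pre: A 45, B 65; post: A 90, B 65
  expect_equal(tab$rows$pre, c(45, 65))
  expect_equal(tab$rows$post, c(90, 65))
  expect_equal(tab$rows$percent_change, c(100, 0))
  expect_equal(tab$average, 50)
  # identical pre and post -> all-zero change column
  same <- build_outcome_table(pre, pre)
  expect_equal(same$rows$percent_change, c(0, 0))
  # unmatched participant id is named
  expect_error(build_outcome_table(pre, post[post$participant_id != "B", ]),
               "unmatched participant id: B")
})

test_that("ICC(2,1) matches the aov mean-squares decomposition to 1e-9", {
  s1 <- c(10.2, 11.5, 9.8, 14.0, 12.2, 10.9)
  s2 <- c(10.9, 11.1, 10.4, 13.1, 12.9, 11.3)
  rel <- icc_test_retest(s1, s2)
  # independent route: two-way ANOVA mean squares via stats::aov
  df <- data.frame(score = c(s1, s2),
                   subject = factor(rep(1:6, 2)),
                   session = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(score ~ subject + session, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(rel$icc, icc_oracle, tolerance = 1e-9)
  # SEM / MDC invariants
  expect_equal(rel$sem, stats::sd(c(s1, s2)) * sqrt(1 - rel$icc), tolerance = 1e-9)
  expect_equal(rel$mdc, 1.96 * sqrt(2) * rel$sem, tolerance = 1e-12)
  expect_equal(rel$mdc_pct_of_mean, 100 * rel$mdc / mean(c(s1, s2)), tolerance = 1e-12)
})

test_that("ICC degenerate and identity cases behave as specified", {
  s <- c(10.2, 11.5, 9.8, 14.0, 12.2, 10.9)
  # retest identical to test -> ICC 1, MDC 0
  rel <- icc_test_retest(s, s)
  expect_equal(rel$icc, 1)
  expect_equal(rel$mdc, 0)
  # shift invariance: adding a constant to all scores of both sessions
  s2 <- s + stats::rnorm(6, 0, 0.5)
  expect_equal(icc_test_retest(s + 100, s2 + 100)$icc,
               icc_test_retest(s, s2)$icc, tolerance = 1e-9)
  # zero total variance is flagged degenerate
  flat <- icc_test_retest(rep(3, 5), rep(3, 5))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$icc))
  expect_error(icc_test_retest(1:2, 1:2), "at least 3")
})

test_that("ICC is near zero for independent noise with no subject variance", {
  set.seed(23)
  a <- stats::rnorm(200)
  b <- stats::rnorm(200)
  expect_lt(abs(icc_test_retest(a, b)$icc), 0.2)
})

test_that("fixture tables carry the printed cells, averages and errata", {
  t3 <- cue_task_table("soccer")
  expect_equal(t3$sr_pre, c(45, 70, 54, 93, 30, 55))
  expect_equal(attr(t3, "printed_average")[["sr_change"]], 65)
  expect_equal(attr(cue_task_table("rotation"), "rt_change_convention"), "reduction")
  # corrected tables apply exactly the catalogued corrections
  t5 <- cue_task_table("rotation", corrected = TRUE)
  expect_equal(t5$sr_change, c(35, 36, 11, 0, 0, 8))
  expect_equal(t5$rt_change, c(4, 34, 18, 15, 19, 12))
  pd <- cue_pdms(corrected = TRUE)
  expect_equal(pd$vmi_post[1], 120)
  # every errata row disagrees with its printed cell by design
  err <- cue_errata()
  expect_true(all(err$printed != err$recomputed))
  tdir <- withr::local_tempdir()
  write_cue_fixtures(tdir)
  expect_identical(nrow(utils::read.csv(file.path(tdir, "table1_participants.csv"))), 6L)
})
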