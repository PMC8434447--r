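# Worked-example fixtures: the published six-child telerehabilitation pilot
# tables (demographics, PDMS-2 subtest scores, and the three computerized
# upper-extremity object-manipulation tasks), transcribed cell by cell as
# printed. They drive the outcome-table worked examples and tests. Known
# internal inconsistencies of the printed tables are catalogued in
# cue_errata() and are never silently corrected; pass `corrected = TRUE` to
# apply the documented corrections.

#' Pilot-study fixture tables
#'
#' `cue_participants()` returns the six participants' demographics (age,
#' gender, GMFCS and MACS levels). `cue_pdms()` returns the PDMS-2 grasp and
#' visual-motor-integration (VMI) subtest pre/post scores with printed
#' percent changes. `cue_task_table()` returns the pre/post success rate
#' (`sr`, %) and response time (`rt`, ms) of one object manipulation task
#' (`"soccer"`: ball rolling, `"cone"`: pronation-supination,
#' `"rotation"`: two-finger fine rotation), each value the average of the two
#' practiced movement directions. In the fine rotation table the printed
#' response-time change column is a percent *reduction* (positive =
#' faster); the other tables print signed percent change.
#'
#' @param corrected Apply the documented corrections from [cue_errata()]
#'   (default `FALSE`: cells exactly as printed, including a transcription
#'   error in one VMI score).
#' @return A tibble; printed Average-row values are kept in the
#'   `printed_average` attribute.
#' @export
cue_participants <- function() {
  tibble::tibble(
    id = paste0("P", 1:6),
    age_years = c(12, 10, 8, 7, 8, 5),
    gender = c("M", "M", "M", "F", "F", "M"),
    gmfcs = c("II", "I", "I", "II", "II", "II"),
    macs = c("III", "II", "II", "III", "III", "III")
  )
}

#' @rdname cue_participants
#' @export
cue_pdms <- function(corrected = FALSE) {
  tb <- tibble::tibble(
    id = paste0("P", 1:6),
    grasp_pre = c(46, 47, 44, 46, 44, 44),
    grasp_post = c(52, 52, 50, 51, 49, 50),
    grasp_change = c(13, 11, 14, 11, 11, 14),
    vmi_pre = c(110, 120, 116, 120, 126, 113),
    vmi_post = c(1120, 130, 125, 131, 134, 127),
    vmi_change = c(9, 8, 8, 9, 6, 12)
  )
  if (corrected) tb$vmi_post[1] <- 120
  attr(tb, "printed_average") <- c(grasp_change = 12, vmi_change = 9)
  tb
}

#' @rdname cue_participants
#' @param task One of `"soccer"`, `"cone"`, `"rotation"`.
#' @export
cue_task_table <- function(task = c("soccer", "cone", "rotation"),
                           corrected = FALSE) {
  task <- match.arg(task)
  tb <- switch(task,
    soccer = tibble::tibble(
      id = paste0("P", 1:6),
      sr_pre = c(45, 70, 54, 93, 30, 55),
      sr_post = c(87, 78, 66, 93, 84, 100),
      sr_change = c(93, 11, 22, 0, 180, 82),
      rt_pre = c(572, 436, 453, 570, 732, 687),
      rt_post = c(535, 359, 470, 527, 527, 532),
      rt_change = c(-6, -18, 4, -8, -28, -23)
    ),
    cone = tibble::tibble(
      id = paste0("P", 1:6),
      sr_pre = c(42, 53, 45, 71, 57, 90),
      sr_post = c(66, 88, 60, 95, 100, 90),
      sr_change = c(57, 66, 33, 34, 75, 0),
      rt_pre = c(415, 370, 497, 510, 565, 578),
      rt_post = c(353, 334, 451, 475, 521, 411),
      rt_change = c(-16, -10, -9, -7, -8, -29)
    ),
    rotation = tibble::tibble(
      id = paste0("P", 1:6),
      sr_pre = c(52, 70, 62, 45, 75, 74),
      sr_post = c(70, 95, 69, 45, 75, 80),
      sr_change = c(33, 34, 11, 80, 13, 9),
      rt_pre = c(520, 665, 830, 540, 650, 625),
      rt_post = c(500, 440, 680, 460, 526, 552),
      rt_change = c(4, 34, 18, 18, 19, 12)
    )
  )
  attr(tb, "printed_average") <- switch(task,
    soccer = c(sr_change = 65, rt_change = -13),
    cone = c(sr_change = 44, rt_change = -13),
    rotation = c(sr_change = 30, rt_change = 18)
  )
  attr(tb, "rt_change_convention") <-
    if (task == "rotation") "reduction" else "signed"
  if (corrected) {
    err <- cue_errata()
    err <- err[err$table == paste0("task_", task), ]
    for (i in seq_len(nrow(err))) {
      tb[[err$column[i]]][match(err$id[i], tb$id)] <- err$recomputed[i]
    }
  }
  tb
}

#' Catalogue of printed-table inconsistencies
#'
#' Cells of the published tables that disagree with recomputation from their
#' own pre/post cells (or are evident transcription errors). `recomputed` is
#' the value implied by the pre/post cells under round-half-away-from-zero
#' integer percent; for the VMI score it is the plausible intended score.
#'
#' @return A tibble with columns `table`, `id`, `column`, `printed`,
#'   `recomputed`, `note`.
#' @export
cue_errata <- function() {
  tibble::tribble(
    ~table, ~id, ~column, ~printed, ~recomputed, ~note,
    "pdms", "P1", "vmi_post", 1120, 120,
      "post score 1120 is out of range for the 72-item subtest; 120 matches the printed 9% change",
    "task_cone", "P1", "rt_change", -16, -15,
      "415 -> 353 recomputes to -15; printed cell is off by one rounding step",
    "task_rotation", "P1", "sr_change", 33, 35,
      "52 -> 70 recomputes to +35",
    "task_rotation", "P2", "sr_change", 34, 36,
      "70 -> 95 recomputes to +36",
    "task_rotation", "P4", "sr_change", 80, 0,
      "45 -> 45 is no change; printed 80 is inconsistent with its own cells",
    "task_rotation", "P5", "sr_change", 13, 0,
      "75 -> 75 is no change; printed 13 is inconsistent with its own cells",
    "task_rotation", "P6", "sr_change", 9, 8,
      "74 -> 80 recomputes to +8",
    "task_rotation", "P4", "rt_change", 18, 15,
      "540 -> 460 recomputes to a 15% reduction"
  )
}

#' Write the pilot-study fixture tables as CSV files
#'
#' Materializes the five worked-example tables (participants, PDMS-2 scores
#' and the three task tables, as printed) plus the errata catalogue into a
#' directory, for use as test fixtures or CLI inputs.
#'
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cue_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cue_participants(), file.path(dir, "table1_participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cue_pdms(), file.path(dir, "table2_pdms.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cue_task_table("soccer"), file.path(dir, "table3_soccer.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cue_task_table("cone"), file.path(dir, "table4_cone.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cue_task_table("rotation"), file.path(dir, "table5_rotation.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cue_errata(), file.path(dir, "errata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
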