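test_that("event log round-trips through CSV preserving all fields", {
  path <- two_solver_log()
  log <- read_event_log(path)
  expect_s3_class(log, "event_log")
  out <- tempfile(fileext = ".csv")
  write_event_log(log, out)
  log2 <- read_event_log(out)
  expect_equal(as.data.frame(log), as.data.frame(log2))
})

test_that("malformed rows are rejected with their line number", {
  rows <- rbind(ev_row(0, "A", "detection"),
                ev_row(10, "A", "door_open", latch = "H"),
                ev_row(20, "A", "door_open", latch = "H"))
  rows$latch_type[3] <- "X"   # data row 3 = file line 4
  expect_error(read_event_log(write_events_csv(rows)),
               "unknown latch code.*line.*4")
  rows2 <- rbind(ev_row(0, "A", "detection"))
  rows2$event_type <- "teleport"
  expect_error(read_event_log(write_events_csv(rows2)), "event_type")
  rows3 <- ev_row(5, "A", "door_open", latch = "H")
  rows3$door_id <- 99L
  expect_error(read_event_log(write_events_csv(rows3)), "door_id")
  expect_error(read_event_log(tempfile()), "not found")
})

test_that("shuffled rows are regrouped chronologically per (site, night) with a warning", {
  rows <- rbind(ev_row(0, "A", "detection", night = "N1"),
                ev_row(50, "A", "detection", night = "N1"),
                ev_row(0, "B", "detection", night = "N2"),
                ev_row(30, "B", "detection", night = "N2"))
  set.seed(4)
  shuffled <- rows[c(4, 1, 3, 2), ]
  expect_warning(log <- read_event_log(write_events_csv(shuffled)),
                 "not chronological")
  expect_equal(log$night_id, c("N1", "N1", "N2", "N2"))
  expect_true(!is.unsorted(log$timestamp[log$night_id == "N1"]))
  # 3-row well-formed file parses to 3 records without warnings
  expect_silent(log3 <- read_event_log(write_events_csv(rows[1:3, ])))
  expect_equal(nrow(log3), 3)
})

test_that("segmentation splits on the absence threshold with a closed boundary", {
  rows <- rbind(ev_row(0, "A", "detection"),
                ev_row(30, "A", "detection"),
                ev_row(100, "A", "detection"))
  tr <- segment_trials(read_event_log(write_events_csv(rows)))
  expect_equal(nrow(tr), 2)           # 70 s gap >= 60 splits
  expect_equal(tr$n_events, c(2L, 1L))
  # a gap of exactly 60 s starts a new trial
  rows60 <- rbind(ev_row(0, "A", "detection"),
                  ev_row(60, "A", "detection"))
  expect_equal(nrow(segment_trials(read_event_log(write_events_csv(rows60)))), 2)
  # 59 s stays in one trial
  rows59 <- rbind(ev_row(0, "A", "detection"),
                  ev_row(59, "A", "detection"))
  expect_equal(nrow(segment_trials(read_event_log(write_events_csv(rows59)))), 1)
  # single event, empty log
  single <- segment_trials(read_event_log(write_events_csv(ev_row(0, "A", "detection"))))
  expect_equal(nrow(single), 1)
  expect_equal(single$n_events, 1L)
})

test_that("segmentation partitions every identified individual's events exactly once", {
  path <- two_solver_log()
  log <- read_event_log(path)
  tr <- segment_trials(log)
  known <- log[!is.na(log$individual_id) & log$individual_id != "UNKNOWN" &
                 log$event_type != "rebait", ]
  expect_equal(sum(tr$n_events), nrow(known))
  # trial indices chronological per individual
  for (id in unique(tr$individual_id)) {
    d <- tr[tr$individual_id == id, ]
    d <- d[order(d$start), ]
    expect_equal(d$trial_index, seq_len(nrow(d)))
  }
  # cumulative prior openings
  a <- tr[tr$individual_id == "A", ]
  a <- a[order(a$trial_index), ]
  expect_equal(a$doors_opened_to_date, c(0L, 6L))
  # per-latch counts over individuals sum to all identified openings
  sv <- classify_solvers(tr)
  expect_equal(sum(sv[, paste0("n_", latch_alphabet())]),
               sum(known$event_type == "door_open"))
})

test_that("solver classification applies the three-door criterion per latch", {
  mk <- function(latches_by_trial, id = "Z") {
    rows <- do.call(rbind, lapply(seq_along(latches_by_trial), function(i) {
      ev_openings((i - 1) * 1000, id, latches_by_trial[[i]])
    }))
    segment_trials(read_event_log(write_events_csv(rows)))
  }
  s1 <- classify_solvers(mk(list(c("H", "H"), "H")))
  expect_true(s1$is_solver)
  expect_equal(s1$solved_latches, "H")
  expect_false(s1$is_flexible)
  s2 <- classify_solvers(mk(list(c("H", "H", "S", "S"))))
  expect_false(s2$is_solver)
  s3 <- classify_solvers(mk(list(c("H", "H", "H", "S", "S", "S"),
                                 c("V", "V", "V"))))
  expect_true(s3$is_flexible)
  expect_equal(s3$n_latches_solved, 3)
  expect_equal(nrow(classify_solvers(segment_trials(
    read_event_log(write_events_csv(ev_row(0, NA, "rebait")))))), 0)
})

test_that("box state tracks openings and resets at rebaits", {
  rows <- rbind(ev_row(0, NA, "rebait"),
                ev_row(10, "A", "door_open", latch = "S", door = 5L),
                ev_row(20, NA, "rebait"),
                ev_row(30, "A", "detection"))
  ann <- track_box_state(read_event_log(write_events_csv(rows)))
  expect_equal(ann$doors_open_before, c(0L, 0L, 0L, 0L))
  expect_true(ann$box_unopened_before[4])       # reset by second rebait
  expect_equal(ann$bait_cycle, c(2L, 2L, 3L, 3L))
  # without any rebait the box starts all-closed
  rows2 <- rbind(ev_row(0, "A", "door_open", latch = "S", door = 5L),
                 ev_row(30, "A", "door_open", latch = "S", door = 6L))
  ann2 <- track_box_state(read_event_log(write_events_csv(rows2)))
  expect_equal(ann2$doors_open_before, c(0L, 1L))
  # reopening an open door warns and leaves the state unchanged
  rows3 <- rbind(ev_row(0, "A", "door_open", latch = "S", door = 5L),
                 ev_row(30, "A", "door_open", latch = "S", door = 5L),
                 ev_row(50, "A", "door_open", latch = "S", door = 6L))
  expect_warning(ann3 <- track_box_state(read_event_log(write_events_csv(rows3))),
                 "already-open")
  expect_equal(ann3$doors_open_before, c(0L, 1L, 1L))
})

test_that("condition classification distinguishes unrestricted from competitive trials", {
  log <- read_event_log(two_solver_log())
  tr <- segment_trials(log)
  sv <- classify_solvers(tr)
  tr <- classify_condition(tr, log, sv)
  get <- function(id, idx) tr[tr$individual_id == id & tr$trial_index == idx, ]
  # A alone at a freshly baited box
  expect_equal(get("A", 1)$condition, "unrestricted")
  expect_true(get("A", 1)$first_arrival)
  # A joined by solver B during its second trial
  expect_equal(get("A", 2)$condition, "competitive")
  expect_true(get("A", 2)$joined_by_solver)
  # B arrived at a partially solved box
  expect_equal(get("B", 1)$condition, "competitive")
  expect_false(get("B", 1)$first_arrival)
  # B alone on night 2
  expect_equal(get("B", 2)$condition, "unrestricted")
  # C is not a solver; its trials are flagged
  expect_false(any(tr$is_solver[tr$individual_id == "C"]))
})

test_that("work-time bins follow the ordinal scale with the documented gap rule", {
  expect_equal(bin_work_time(3), 1L)
  expect_equal(bin_work_time(30.5), 3L)
  expect_equal(bin_work_time(31), 4L)
  expect_equal(bin_work_time(c(0, 4.9, 5, 15.9, 16, 30.9, 31, 100)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_true(is.na(bin_work_time(NA)))
  expect_error(bin_work_time(-1), "non-negative")
})

test_that("sequence extraction applies the length, experience, condition and year filters", {
  log <- read_event_log(two_solver_log())
  tr <- segment_trials(log)
  sv <- classify_solvers(tr)
  tr <- classify_condition(tr, log, sv)
  seqs <- extract_latch_sequences(tr, sv)
  # only trials with >= 6 prior doors qualify
  expect_setequal(paste(seqs$individual_id, seqs$trial_index),
                  c("A 2", "B 2"))
  expect_equal(seqs$sequence[seqs$individual_id == "A"], "SVSVVS")
  uns <- extract_latch_sequences(tr, sv, condition = "unrestricted")
  expect_equal(uns$individual_id, "B")
  # raising the length filter empties the set with a message
  expect_message(none <- extract_latch_sequences(tr, sv, min_length = 20),
                 "no trials satisfy")
  expect_equal(nrow(none), 0)
})

test_that("first-year filter drops later-year trials", {
  rows <- rbind(ev_openings(0, "A", rep("S", 6)),
                ev_openings(0, "A", rep("H", 7), night = "N9"))
  rows$timestamp[7:13] <- sub("^2016", "2017", rows$timestamp[7:13])
  log <- read_event_log(write_events_csv(rows))
  tr <- segment_trials(log)
  sv <- classify_solvers(tr)
  tr <- classify_condition(tr, log, sv)
  with_filter <- extract_latch_sequences(tr, sv, min_doors_to_date = 0)
  expect_equal(with_filter$sequence, "SSSSSS")
  without <- extract_latch_sequences(tr, sv, min_doors_to_date = 0,
                                     first_year_only = FALSE)
  expect_equal(nrow(without), 2)
})

test_that("final-trials subset takes the last k first-arrival trials and tabulates latches", {
  # one solver with 9 qualifying trials: nights far apart so each trial
  # is its own bait cycle
  rows <- do.call(rbind, lapply(1:9, function(i) {
    rbind(ev_row((i - 1) * 5000, NA, "rebait"),
          ev_openings((i - 1) * 5000 + 10, "A",
                      c("S", "S", "S", if (i > 5) "H" else "V")))
  }))
  log <- read_event_log(write_events_csv(rows))
  tr <- segment_trials(log)
  sv <- classify_solvers(tr)
  tr <- classify_condition(tr, log, sv)
  ft <- final_trials_subset(tr, sv, k = 5)
  expect_equal(nrow(ft$trials), 5)
  expect_equal(sort(ft$trials$trial_index), 5:9)
  expect_equal(unname(ft$first_latch_counts["S"]), 5L)
  expect_equal(unname(ft$total_latch_counts[c("S", "H", "V")]),
               c(15L, 4L, 1L))
  # fewer than k trials: all returned with a warning
  short <- tr[tr$trial_index <= 3, ]
  attr(short, "openings") <- trial_openings(tr)
  expect_warning(ft2 <- final_trials_subset(short, sv, k = 5),
                 "only 3")
  expect_equal(nrow(ft2$trials), 3)
})
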